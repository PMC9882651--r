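#' Motion recording container
#'
#' A `motion_recording` is a data.frame with one row per sample and columns
#' `t` (s, strictly increasing, uniform), `qw,qx,qy,qz` (unit quaternion,
#' Hamilton scalar-first, passive world-to-sensor), `vx,vy,vz` (world-frame
#' linear velocity, m/s), `ax,ay,az` (sensor-frame total linear acceleration,
#' gravitational + inertial, m/s^2), `wx,wy,wz` (sensor-frame angular
#' velocity, rad/s), `confidence` (integer 0-3) and `segment`
#' (one of `"data"`, `"static_cal"`, `"nod_cal"`, `"shake_cal"`).
#' The sampling rate is stored in `attr(, "sample_rate")`.
#'
#' @param df data.frame with the columns above.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `motion_recording`.
#' @export
motion_recording <- function(df, sample_rate) {
  req <- c("t", "qw", "qx", "qy", "qz", "vx", "vy", "vz",
           "ax", "ay", "az", "wx", "wy", "wz", "confidence", "segment")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, c(req, setdiff(names(df), req))]
  validate_recording(df)
  structure(df, sample_rate = sample_rate,
            class = c("motion_recording", "data.frame"))
}

validate_recording <- function(df) {
  qn <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  if (any(abs(qn - 1) > 1e-6))
    stop("quaternion norms deviate from 1 by more than 1e-6")
  if (!all(df$confidence %in% 0:3))
    stop("confidence must be an integer in 0..3")
  if (!all(df$segment %in% c("data", "static_cal", "nod_cal", "shake_cal")))
    stop("unknown segment label")
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("time must be strictly increasing")
  invisible(df)
}

#' Channel accessors for a motion recording
#'
#' Convenience extractors: the quaternion, world-velocity, total-acceleration
#' and angular-velocity channels as n x 3 (or n x 4) matrices, the
#' velocity-norm (speed) series, and the sampling rate.
#'
#' @param rec a `motion_recording`.
#' @return a matrix, numeric vector, or scalar as appropriate.
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
rec_quat <- function(rec) cbind(rec$qw, rec$qx, rec$qy, rec$qz)
#' @rdname recording-accessors
#' @export
rec_vel <- function(rec) cbind(rec$vx, rec$vy, rec$vz)
#' @rdname recording-accessors
#' @export
rec_acc <- function(rec) cbind(rec$ax, rec$ay, rec$az)
#' @rdname recording-accessors
#' @export
rec_omega <- function(rec) cbind(rec$wx, rec$wy, rec$wz)
#' @rdname recording-accessors
#' @export
rec_speed <- function(rec) sqrt(rec$vx^2 + rec$vy^2 + rec$vz^2)
#' @rdname recording-accessors
#' @export
rec_rate <- function(rec) attr(rec, "sample_rate")

#' @export
print.motion_recording <- function(x, ...) {
  fs <- rec_rate(x)
  cat(sprintf("<motion_recording> %d samples at %.4g Hz (%.2f min)\n",
              nrow(x), fs, nrow(x) / fs / 60))
  seg <- table(x$segment)
  cat("  segments:", paste(sprintf("%s=%d", names(seg), seg), collapse = ", "),
      "\n")
  cat(sprintf("  confidence<3: %d samples; peak speed %.2f m/s\n",
              sum(x$confidence < 3), max(rec_speed(x))))
  invisible(x)
}

#' Write a recording as delimited text with a JSON config sidecar
#'
#' One row per sample, tab-separated, with a header line. If the recording
#' carries a simulation config (`attr(, "sim_config")`) it is written next to
#' the data file as `<path>.json`.
#'
#' @param rec a `motion_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(rec)[, c("t", "qw", "qx", "qy", "qz", "vx", "vy", "vz",
                               "ax", "ay", "az", "wx", "wy", "wz",
                               "confidence", "segment")]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- attr(rec, "sim_config")
  meta <- list(sample_rate = rec_rate(rec))
  if (!is.null(cfg)) meta$sim_config <- unclass(cfg)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path data file path; the sidecar `<path>.json` supplies the
#'   sampling rate (falling back to the median time step if absent).
#' @return a `motion_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$sample_rate
  } else {
    fs <- 1 / stats::median(diff(df$t))
  }
  motion_recording(df, sample_rate = fs)
}
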