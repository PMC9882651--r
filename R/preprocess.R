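#' @title Exclusion rules and velocity partitioning
#' @description Implements the pre-processing rules applied before any
#'   statistic is computed: calibration segments are excised, frames with
#'   tracking confidence below 3 are excluded, frames with linear-velocity
#'   norm above 3.05 m/s are excluded as tracking artifacts, and retained
#'   frames are partitioned into low (< 0.75 m/s) and high velocity classes.
#'   Each rule yields an independent mask; the final retained set is their
#'   conjunction, so application order is irrelevant.
#' @name preprocess
NULL

#' Confidence filter
#' @param rec a `motion_recording`.
#' @param min_confidence minimum retained confidence (default 3: anything
#'   lower is excluded).
#' @return logical vector, TRUE for retained frames.
#' @export
filter_confidence <- function(rec, min_confidence = 3L) {
  rec$confidence >= min_confidence
}

#' Velocity-artifact filter
#'
#' Frames whose linear-velocity Euclidean norm exceeds the threshold are
#' excluded; a frame exactly at the threshold is retained ("above" excluded).
#'
#' @param rec a `motion_recording`.
#' @param threshold_mps exclusion threshold in m/s.
#' @return logical vector, TRUE for retained frames.
#' @export
filter_speed <- function(rec, threshold_mps = 3.05) {
  rec_speed(rec) <= threshold_mps
}

#' Calibration-segment excision
#'
#' @param rec a `motion_recording`.
#' @param windows list of time intervals `c(t0, t1)` (s); overlapping windows
#'   are treated as their union. NULL entries are ignored. If `windows` is
#'   NULL, segment labels (`!= "data"`) define the calibration set.
#' @return logical vector, TRUE for frames outside every window.
#' @export
excise_calibration <- function(rec, windows = NULL) {
  if (is.null(windows)) return(rec$segment == "data")
  inside <- rep(FALSE, nrow(rec))
  for (w in windows) {
    if (is.null(w)) next
    inside <- inside | (rec$t >= w[1] & rec$t < w[2])
  }
  !inside
}

#' Build the combined exclusion mask
#'
#' Applies the three rules (plus optional user-supplied manual exclusion
#' intervals) independently and records, for each excluded frame, the first
#' rule that excludes it, in the fixed precedence calibration > manual >
#' confidence > speed. Retained frames are classed low/high by
#' [partition_velocity()].
#'
#' @param rec a `motion_recording`.
#' @param cal_windows calibration windows for [excise_calibration()] (NULL:
#'   use segment labels).
#' @param manual_windows optional list of manually flagged intervals.
#' @param min_confidence,speed_threshold_mps,velocity_cutoff_mps rule
#'   parameters.
#' @return object of class `clean_mask`: list with `retained` (logical),
#'   `reason` (character, NA for retained frames) and `velocity_class`
#'   (character `"low"`/`"high"`, NA for excluded frames).
#' @export
clean_mask <- function(rec, cal_windows = NULL, manual_windows = NULL,
                       min_confidence = 3L, speed_threshold_mps = 3.05,
                       velocity_cutoff_mps = 0.75) {
  keep_cal <- excise_calibration(rec, cal_windows)
  keep_man <- if (is.null(manual_windows)) rep(TRUE, nrow(rec)) else
    excise_calibration(rec, manual_windows)
  keep_conf <- filter_confidence(rec, min_confidence)
  keep_speed <- filter_speed(rec, speed_threshold_mps)
  retained <- keep_cal & keep_man & keep_conf & keep_speed
  reason <- rep(NA_character_, nrow(rec))
  reason[!keep_speed] <- "speed"
  reason[!keep_conf] <- "confidence"
  reason[!keep_man] <- "manual"
  reason[!keep_cal] <- "calibration"
  reason[retained] <- NA_character_
  mask <- structure(list(retained = retained, reason = reason,
                         velocity_class = rep(NA_character_, nrow(rec))),
                    class = "clean_mask")
  partition_velocity(rec, mask, velocity_cutoff_mps)
}

#' Partition retained frames into low/high velocity classes
#'
#' A retained frame is `"low"` when its velocity norm is strictly below the
#' cutoff and `"high"` otherwise (a frame exactly at the cutoff is high).
#'
#' @param rec a `motion_recording`.
#' @param mask a `clean_mask`.
#' @param cutoff_mps class boundary in m/s.
#' @return the mask with `velocity_class` filled in.
#' @export
partition_velocity <- function(rec, mask, cutoff_mps = 0.75) {
  sp <- rec_speed(rec)
  cls <- ifelse(sp < cutoff_mps, "low", "high")
  cls[!mask$retained] <- NA_character_
  mask$velocity_class <- cls
  mask
}

#' @export
print.clean_mask <- function(x, ...) {
  n <- length(x$retained)
  cat(sprintf("<clean_mask> %d frames, %d retained (%.2f%%)\n",
              n, sum(x$retained), 100 * mean(x$retained)))
  tab <- table(x$reason[!x$retained])
  if (length(tab))
    cat("  excluded:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%s=%d",
                                  names(table(x$velocity_class)),
                                  table(x$velocity_class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Retention report
#'
#' @param mask a `clean_mask`.
#' @param sample_rate sampling rate in Hz.
#' @return list: hours retained, hours and fraction per velocity class
#'   (fractions of retained data, summing to 1), and exclusion counts per
#'   reason.
#' @export
retention_summary <- function(mask, sample_rate) {
  n_ret <- sum(mask$retained)
  h <- function(k) k / sample_rate / 3600
  n_low <- sum(mask$velocity_class == "low", na.rm = TRUE)
  n_high <- sum(mask$velocity_class == "high", na.rm = TRUE)
  reasons <- c("calibration", "manual", "confidence", "speed")
  excl <- vapply(reasons, function(r) sum(mask$reason == r, na.rm = TRUE), 0L)
  list(hours_retained = h(n_ret),
       hours_low = h(n_low), hours_high = h(n_high),
       fraction_low = if (n_ret > 0) n_low / n_ret else 0,
       fraction_high = if (n_ret > 0) n_high / n_ret else 0,
       frames_retained = n_ret, frames_total = length(mask$retained),
       excluded_counts = as.list(excl))
}
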