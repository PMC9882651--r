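#' @title Sensor-to-head frame alignment
#' @description Estimates the rotation from the sensor frame to the
#'   anatomically referenced head frame from a calibration protocol: nodding
#'   (pitch) and head-shaking (yaw) movements define the interaural and
#'   dorsal-ventral axes; a static segment held with Reid's baseline
#'   horizontal anchors the pitch offset to gravity.
#' @name frame_alignment
NULL

#' Alignment result
#'
#' @param R_sensor_head 3 x 3 proper rotation mapping sensor-frame vectors to
#'   the head frame (X nasal-occipital forward, Y interaural left, Z up).
#' @param axis_residual_deg angle (deg) between the recovered shake axis and
#'   its orthogonalized version.
#' @param reid_pitch_offset_deg pitch rotation (deg, about head +Y) applied to
#'   level the head horizontal plane against measured gravity; `NA` for a
#'   partial (axes-only) result.
#' @return object of class `alignment_result`.
#' @export
alignment_result <- function(R_sensor_head, axis_residual_deg = 0,
                             reid_pitch_offset_deg = NA_real_) {
  R <- R_sensor_head
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R_sensor_head must be a proper rotation (orthonormal, det +1)")
  structure(list(R_sensor_head = R, axis_residual_deg = axis_residual_deg,
                 reid_pitch_offset_deg = reid_pitch_offset_deg),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> rotation %.3f deg from identity; axis residual %.4f deg\n",
    rotation_angle_deg(x$R_sensor_head), x$axis_residual_deg))
  if (!is.na(x$reid_pitch_offset_deg))
    cat(sprintf("  Reid pitch offset %.3f deg\n", x$reid_pitch_offset_deg))
  invisible(x)
}

principal_axis <- function(omega) {
  ev <- eigen(crossprod(omega), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  axis / sqrt(sum(axis^2))
}

#' Estimate the sensor-to-head axis rotation from calibration movements
#'
#' The dominant rotation axis of each angular-velocity series (first
#' principal direction of the sample cloud, sign fixed by positive projection
#' onto its nominal head axis) gives the head interaural (+Y, from nodding)
#' and dorsal-ventral (+Z, from shaking) axes in sensor coordinates. The yaw
#' axis is orthogonalized against the pitch axis and the nasal-occipital axis
#' completes the right-handed triad.
#'
#' @param omega_nod n x 3 sensor-frame angular velocity (rad/s) during
#'   nodding (at least ~2 s of movement).
#' @param omega_shake same, during head shaking.
#' @return partial [alignment_result()] (no Reid offset yet).
#' @export
estimate_axis_rotation <- function(omega_nod, omega_shake) {
  omega_nod <- as.matrix(omega_nod); omega_shake <- as.matrix(omega_shake)
  if (nrow(omega_nod) < 20L || nrow(omega_shake) < 20L)
    stop("calibration series too short")
  if (mean(sqrt(rowSums(omega_nod^2))) < 0.05 ||
      mean(sqrt(rowSums(omega_shake^2))) < 0.05)
    stop("near-zero angular velocity power in a calibration series")
  y_axis <- principal_axis(omega_nod)
  if (y_axis[2] < 0) y_axis <- -y_axis
  z_raw <- principal_axis(omega_shake)
  if (z_raw[3] < 0) z_raw <- -z_raw
  sep <- acos(pmin(1, abs(sum(y_axis * z_raw)))) * 180 / pi
  if ((90 - sep) > 60)
    stop("degenerate calibration: nod and shake axes separated by < 30 deg")
  z_axis <- z_raw - sum(z_raw * y_axis) * y_axis
  z_axis <- z_axis / sqrt(sum(z_axis^2))
  x_axis <- cross3(matrix(y_axis, 1), matrix(z_axis, 1))[1, ]
  residual <- acos(pmin(1, sum(z_raw * z_axis))) * 180 / pi
  alignment_result(rbind(x_axis, y_axis, z_axis, deparse.level = 0),
                   axis_residual_deg = residual)
}

#' Estimate the Reid's-baseline pitch offset from a static segment
#'
#' Rotates the time-averaged measured gravity direction by the axis rotation,
#' then returns the rotation about the (already aligned) head pitch axis that
#' makes the head horizontal plane perpendicular to gravity.
#'
#' @param a_static n x 3 sensor-frame total acceleration (m/s^2) during the
#'   static Reid's-baseline segment (>= 5 s; mean norm within 20% of 9.81).
#' @param R_axes 3 x 3 rotation from [estimate_axis_rotation()].
#' @return pitch offset in degrees (rotation about head +Y).
#' @export
estimate_reid_pitch_offset <- function(a_static, R_axes) {
  a_static <- as.matrix(a_static)
  if (nrow(a_static) < 20L) stop("static window too short")
  g_bar <- colMeans(a_static)
  nrm <- sqrt(sum(g_bar^2))
  if (abs(nrm - 9.81) > 0.2 * 9.81)
    stop("mean static acceleration norm deviates from gravity by > 20%")
  if (stats::sd(sqrt(rowSums(a_static^2))) > 0.5)
    warning("motion detected during the static calibration segment")
  g_head <- as.numeric(R_axes %*% g_bar)
  atan2(g_head[1], -g_head[3]) * 180 / pi
}

rot_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}

#' Estimate a full alignment from calibration windows of a recording
#'
#' Runs [estimate_axis_rotation()] on the nod/shake windows and, if a static
#' window is provided, [estimate_reid_pitch_offset()]; otherwise
#' `reid_pitch_offset_deg` (e.g. carried over from an earlier calibration)
#' must be supplied.
#'
#' @param rec a `motion_recording`.
#' @param windows list with elements `nods`, `shakes` (each `c(t0, t1)` in s)
#'   and optionally `static`.
#' @param reid_pitch_offset_deg offset to reuse when `windows$static` is NULL.
#' @param trim_s seconds trimmed from each end of every window before
#'   estimation, so transitions into/out of the calibration movements do not
#'   contaminate the axis and gravity estimates.
#' @return an [alignment_result()].
#' @export
estimate_alignment <- function(rec, windows, reid_pitch_offset_deg = NULL,
                               trim_s = 1) {
  in_win <- function(w) rec$t >= (w[1] + trim_s) & rec$t < (w[2] - trim_s)
  axes <- estimate_axis_rotation(rec_omega(rec)[in_win(windows$nods), ],
                                 rec_omega(rec)[in_win(windows$shakes), ])
  if (!is.null(windows$static)) {
    off <- estimate_reid_pitch_offset(rec_acc(rec)[in_win(windows$static), ],
                                      axes$R_sensor_head)
  } else if (!is.null(reid_pitch_offset_deg)) {
    off <- reid_pitch_offset_deg
  } else {
    stop("no static window and no carried-over Reid pitch offset")
  }
  alignment_result(rot_y(off) %*% axes$R_sensor_head,
                   axis_residual_deg = axes$axis_residual_deg,
                   reid_pitch_offset_deg = off)
}

#' Apply an alignment to a recording
#'
#' Rotates all sensor-frame channels (total acceleration, angular velocity)
#' into the head frame and left-composes the orientation quaternions so they
#' map world to head. World-frame velocity is unchanged.
#'
#' @param rec a `motion_recording`.
#' @param align an [alignment_result()].
#' @return the aligned `motion_recording`.
#' @export
apply_alignment <- function(rec, align) {
  R <- align$R_sensor_head
  q_align <- quat_from_matrix(R)
  q_new <- quat_normalize(quat_multiply(q_align, rec_quat(rec)))
  a <- rec_acc(rec) %*% t(R)
  w <- rec_omega(rec) %*% t(R)
  rec$qw <- q_new[, 1]; rec$qx <- q_new[, 2]
  rec$qy <- q_new[, 3]; rec$qz <- q_new[, 4]
  rec$ax <- a[, 1]; rec$ay <- a[, 2]; rec$az <- a[, 3]
  rec$wx <- w[, 1]; rec$wy <- w[, 2]; rec$wz <- w[, 3]
  attr(rec, "alignment") <- align
  rec
}

#' Apply piecewise alignments across periodic re-calibrations
#'
#' Each span between consecutive calibrations is aligned with the rotation
#' estimated from the calibration at its start; the Reid pitch offset is
#' carried forward from the most recent static segment (re-calibrations
#' contain only nod and shake movements). A span whose calibration fails
#' falls back to the previous span's alignment with a warning.
#'
#' @param rec a `motion_recording`.
#' @param windows_list time-ordered list of window sets as in
#'   [estimate_alignment()]; typically the first contains `static`.
#' @return the aligned recording; `attr(, "span_alignments")` holds one
#'   [alignment_result()] per span and `attr(, "span_breaks")` the span start
#'   times (s).
#' @export
apply_recalibrations <- function(rec, windows_list) {
  n_w <- length(windows_list)
  starts <- vapply(windows_list, function(w) {
    min(c(w$static[1], w$nods[1], w$shakes[1]), na.rm = TRUE)
  }, 0)
  if (is.unsorted(starts)) stop("calibration windows must be time-ordered")
  aligns <- vector("list", n_w)
  off <- NULL
  for (k in seq_len(n_w)) {
    aligns[[k]] <- tryCatch(
      estimate_alignment(rec, windows_list[[k]], reid_pitch_offset_deg = off),
      error = function(e) {
        warning(sprintf("calibration %d failed (%s); reusing previous span",
                        k, conditionMessage(e)))
        if (k == 1L) stop("initial calibration failed: ",
                          conditionMessage(e))
        aligns[[k - 1L]]
      })
    off <- aligns[[k]]$reid_pitch_offset_deg
  }
  bounds <- c(0, starts[-1], Inf)
  out <- rec
  q <- rec_quat(rec); a <- rec_acc(rec); w <- rec_omega(rec)
  for (k in seq_len(n_w)) {
    idx <- rec$t >= bounds[k] & rec$t < bounds[k + 1]
    if (!any(idx)) next
    R <- aligns[[k]]$R_sensor_head
    q_align <- quat_from_matrix(R)
    qn <- quat_normalize(quat_multiply(q_align, q[idx, , drop = FALSE]))
    an <- a[idx, , drop = FALSE] %*% t(R)
    wn <- w[idx, , drop = FALSE] %*% t(R)
    out$qw[idx] <- qn[, 1]; out$qx[idx] <- qn[, 2]
    out$qy[idx] <- qn[, 3]; out$qz[idx] <- qn[, 4]
    out$ax[idx] <- an[, 1]; out$ay[idx] <- an[, 2]; out$az[idx] <- an[, 3]
    out$wx[idx] <- wn[, 1]; out$wy[idx] <- wn[, 2]; out$wz[idx] <- wn[, 3]
  }
  attr(out, "span_alignments") <- aligns
  attr(out, "span_breaks") <- starts
  out
}

#' Flatten generator calibration windows into an ordered window list
#'
#' @param cw the `calibration_windows` attribute of a simulated recording.
#' @return list of window sets suitable for [apply_recalibrations()].
#' @export
alignment_windows_list <- function(cw) {
  c(list(list(static = cw$static, nods = cw$nods, shakes = cw$shakes)),
    lapply(cw$recal, function(w) list(static = NULL, nods = w$nods,
                                      shakes = w$shakes)))
}
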