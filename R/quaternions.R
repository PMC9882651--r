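#' @title Quaternion and rotation utilities
#' @description Vectorised Hamilton (scalar-first) quaternion algebra used by
#'   the kinematics pipeline. Quaternions are stored as n x 4 matrices with
#'   columns (w, x, y, z). A recording's orientation quaternion is *passive*
#'   world-to-frame: `quat_rotate(q, v_world)` expresses a world-frame vector
#'   in the sensor (or head) frame.
#' @name quaternions
NULL

#' Normalize quaternions to unit norm
#'
#' @param q numeric n x 4 matrix (or length-4 vector), scalar-first.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_normalize <- function(q) {
  q <- quat_as_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < .Machine$double.eps))
    stop("cannot normalize a zero quaternion")
  q / n
}

quat_as_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L, byrow = TRUE)
  if (ncol(q) != 4L) stop("quaternions must have 4 columns (w, x, y, z)")
  q
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a %*% b`; either argument may be a single quaternion,
#' which is recycled.
#'
#' @param a,b quaternion matrices (n x 4 or 1 x 4), scalar-first.
#' @return n x 4 matrix, the row-wise Hamilton product.
#' @export
quat_multiply <- function(a, b) {
  a <- quat_as_matrix(a); b <- quat_as_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

#' Quaternion conjugate
#' @param q n x 4 quaternion matrix.
#' @return n x 4 matrix with the vector part negated.
#' @export
quat_conjugate <- function(q) {
  q <- quat_as_matrix(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' Quaternion from axis-angle
#'
#' @param axis length-3 rotation axis (need not be unit length).
#' @param angle_rad rotation angle in radians (scalar or vector; a vector
#'   yields one quaternion per angle about the common axis).
#' @return n x 4 quaternion matrix.
#' @export
quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_rad / 2
  cbind(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3],
        deparse.level = 0)
}

#' Rotate vectors by quaternions
#'
#' Applies the rotation represented by each row of `q` to the matching row of
#' `v` (q v q*). Either argument may have a single row.
#'
#' @param q n x 4 unit quaternion matrix.
#' @param v n x 3 matrix of vectors.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_as_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L, byrow = TRUE)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  qv <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (qv x v) + 2 qv x (qv x v)
  t1 <- 2 * cross3(qv, v)
  v + q[, 1] * t1 + cross3(qv, t1)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

#' Rotation matrix of a quaternion
#' @param q a single unit quaternion (length 4 or 1 x 4).
#' @return 3 x 3 proper rotation matrix `R` with `R v == quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  q <- drop(quat_as_matrix(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion of a rotation matrix
#' @param R 3 x 3 proper rotation matrix.
#' @return 1 x 4 unit quaternion (scalar part non-negative).
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(matrix(q, nrow = 1))
}

#' Rotation matrix from an axis-angle misalignment
#'
#' Convenience constructor used to specify sensor-on-head mounting offsets.
#'
#' @param axis length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(axis, angle_deg) {
  quat_to_matrix(quat_from_axis_angle(axis, angle_deg * pi / 180))
}

#' Head-frame Euler angles of world-to-head quaternions
#'
#' Head axis convention: X nasal-occipital (+ forward), Y interaural (+ left),
#' Z dorsal-ventral (+ up); world Z up. Angles follow an intrinsic
#' yaw-pitch-roll (Z-Y'-X'') decomposition with signs chosen so positive pitch
#' is upward (extension; downward pitch negative) and positive roll is
#' left-ear-down. Yaw is positive for leftward (counter-clockwise seen from
#' above) rotation.
#'
#' @param q n x 4 passive world-to-head unit quaternions.
#' @return data.frame with columns `yaw`, `pitch`, `roll` in degrees
#'   (pitch in [-90, 90], yaw/roll in [-180, 180)) and logical `gimbal`
#'   flagging samples with |pitch| > 89.9 deg.
#' @export
quat_to_euler <- function(q) {
  q <- quat_as_matrix(q)
  nq <- sqrt(rowSums(q^2))
  if (any(abs(nq - 1) > 1e-3)) stop("non-unit quaternion (|norm - 1| > 1e-3)")
  q <- q / nq
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # R_bw = R(q) (world -> head, passive); R_wb = t(R_bw).
  # R_wb = Rz(yaw) Ry(-pitch) Rx(-roll) under the sign convention above.
  r31 <- 2 * (x * z + w * y)   # R_wb[3,1] = R_bw[1,3]
  r32 <- 2 * (y * z - w * x)   # R_wb[3,2] = R_bw[2,3]
  r33 <- 1 - 2 * (x^2 + y^2)
  r21 <- 2 * (x * y - w * z)   # R_wb[2,1] = R_bw[1,2]
  r11 <- 1 - 2 * (y^2 + z^2)
  pitch <- asin(pmin(1, pmax(-1, r31)))
  roll <- -atan2(r32, r33)
  yaw <- atan2(r21, r11)
  deg <- 180 / pi
  data.frame(yaw = yaw * deg, pitch = pitch * deg, roll = roll * deg,
             gimbal = abs(pitch * deg) > 89.9)
}

#' World-to-head quaternions from Euler angles
#'
#' Inverse of [quat_to_euler()] under the same axis and sign conventions.
#'
#' @param yaw,pitch,roll angles in degrees (vectors of a common length).
#' @return n x 4 passive world-to-head unit quaternion matrix.
#' @export
euler_to_quat <- function(yaw, pitch, roll) {
  rad <- pi / 180
  qz <- cbind(cos(yaw * rad / 2), 0, 0, sin(yaw * rad / 2))
  qy <- cbind(cos(-pitch * rad / 2), 0, sin(-pitch * rad / 2), 0)
  qx <- cbind(cos(-roll * rad / 2), sin(-roll * rad / 2), 0, 0)
  # q_wb = qz * qy * qx (head -> world); recording stores the passive inverse
  quat_conjugate(quat_multiply(quat_multiply(qz, qy), qx))
}

#' Body-frame angular velocity from a quaternion time series
#'
#' Finite-difference estimate: the relative rotation between consecutive
#' samples is converted to a rotation vector and divided by the sample
#' interval. The last sample repeats the penultimate rate.
#'
#' @param q n x 4 passive world-to-body quaternion series.
#' @param dt sample interval in seconds.
#' @return n x 3 matrix of angular velocity (rad/s) in the body frame.
#' @export
quat_angular_velocity <- function(q, dt) {
  q <- quat_as_matrix(q)
  n <- nrow(q)
  if (n < 2L) stop("need at least 2 samples")
  q1 <- q[-n, , drop = FALSE]
  q2 <- q[-1L, , drop = FALSE]
  rel <- quat_multiply(q2, quat_conjugate(q1))
  flip <- rel[, 1] < 0
  rel[flip, ] <- -rel[flip, ]
  ang <- 2 * atan2(sqrt(rowSums(rel[, 2:4, drop = FALSE]^2)), rel[, 1])
  s <- ifelse(ang > 1e-12, ang / sin(ang / 2), 2)
  # passive convention: q_{t+1} conj(q_t) ~ (1, -omega dt / 2)
  w <- -(rel[, 2:4, drop = FALSE] * s) / dt
  rbind(w, w[n - 1L, , drop = FALSE])
}

#' Angle between two rotations
#' @param R1,R2 3 x 3 rotation matrices.
#' @return geodesic angle in degrees between the two rotations.
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  R <- R1 %*% t(R2)
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, c_ang))) * 180 / pi
}
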