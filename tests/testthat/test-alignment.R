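test_that("axis rotation: aligned calibration gives the identity", {
  cal <- make_cal_omega(diag(3))
  al <- estimate_axis_rotation(cal$nod, cal$shake)
  expect_lt(rotation_angle_deg(al$R_sensor_head), 1e-9)
  expect_lt(al$axis_residual_deg, 1e-9)
})

test_that("axis rotation recovers a known misalignment exactly without noise", {
  R0 <- rotation_from_axis_angle(c(1, 2, 3), 17)
  cal <- make_cal_omega(R0)
  al <- estimate_axis_rotation(cal$nod, cal$shake)
  expect_lt(rotation_angle_deg(al$R_sensor_head, R0) * pi / 180, 1e-6)
})

test_that("axis rotation degenerate inputs are rejected", {
  cal <- make_cal_omega(diag(3))
  expect_error(estimate_axis_rotation(cal$nod, cal$nod), "degenerate")
  expect_error(estimate_axis_rotation(cal$nod * 1e-4, cal$shake),
               "near-zero")
  expect_error(estimate_axis_rotation(cal$nod[1:5, ], cal$shake),
               "too short")
})

test_that("returned rotations are proper orthonormal under noise", {
  set.seed(5)
  for (k in 1:20) {
    axis <- rnorm(3)
    R0 <- rotation_from_axis_angle(axis, runif(1, 0, 25))
    cal <- make_cal_omega(R0, noise_sd = 0.05)
    R <- estimate_axis_rotation(cal$nod, cal$shake)$R_sensor_head
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
    expect_lt(rotation_angle_deg(R, R0), 0.5)
  }
})

test_that("Reid pitch offset matches constructed gravity tilts", {
  flat <- matrix(rep(c(0, 0, -9.81), 300), ncol = 3, byrow = TRUE)
  expect_equal(estimate_reid_pitch_offset(flat, diag(3)), 0)
  tilt <- function(deg) matrix(rep(c(-9.81 * sin(deg * pi / 180), 0,
                                     -9.81 * cos(deg * pi / 180)), 300),
                               ncol = 3, byrow = TRUE)
  # a gravity direction tilted about the pitch axis is recovered exactly
  expect_equal(abs(estimate_reid_pitch_offset(tilt(10), diag(3))), 10,
               tolerance = 1e-9)
  # the returned rotation levels gravity back onto head -Z
  off <- estimate_reid_pitch_offset(tilt(10), diag(3))
  R <- headstats:::rot_y(off)
  g <- drop(R %*% colMeans(tilt(10)))
  expect_equal(g[1], 0, tolerance = 1e-9)
  expect_lt(g[3], 0)
  # norm check and motion warning
  expect_error(estimate_reid_pitch_offset(flat * 2, diag(3)), "norm")
  noisy <- flat + matrix(rnorm(900, sd = 1.0), ncol = 3)
  expect_warning(estimate_reid_pitch_offset(noisy, diag(3)), "motion")
})

test_that("apply_alignment is an isometry with group structure", {
  rec <- simulate_recording(sim_config(seed = 6, duration_s = 90))
  id <- alignment_result(diag(3))
  expect_equal(as.data.frame(apply_alignment(rec, id)), as.data.frame(rec),
               tolerance = 1e-12, ignore_attr = TRUE)
  R <- rotation_from_axis_angle(c(2, -1, 1), 12)
  fwd <- apply_alignment(rec, alignment_result(R))
  back <- apply_alignment(fwd, alignment_result(t(R)))
  expect_equal(back$qw, rec$qw, tolerance = 1e-9)
  expect_equal(back$ax, rec$ax, tolerance = 1e-9)
  expect_equal(back$wz, rec$wz, tolerance = 1e-9)
  expect_equal(sqrt(fwd$ax^2 + fwd$ay^2 + fwd$az^2),
               sqrt(rec$ax^2 + rec$ay^2 + rec$az^2), tolerance = 1e-9)
})

test_that("full calibration recovers the generator misalignment end-to-end", {
  M <- rotation_from_axis_angle(c(1, 2, 3), 17)
  cfg <- sim_config(seed = 5, duration_s = 300,
                    misalignment = list(axis = c(1, 2, 3), angle_deg = 17),
                    artifact_rates = list(confidence_drop_per_hour = 0,
                                          velocity_spike_per_hour = 0))
  rec <- simulate_recording(cfg)
  cw <- attr(rec, "calibration_windows")
  al <- estimate_alignment(rec, list(static = cw$static, nods = cw$nods,
                                     shakes = cw$shakes))
  expect_lt(rotation_angle_deg(al$R_sensor_head, M), 0.5)
  # aligned angles match the generator's head-frame truth
  ang <- angle_series(apply_alignment(rec, al))
  internal <- attr(rec, "internal")
  i <- rec$segment == "data" & abs(internal$pitch) < 80
  expect_lt(max(abs(ang$pitch[i] - internal$pitch[i])), 0.5)
  expect_lt(max(abs(ang$roll[i] - internal$roll[i])), 0.5)
  # gravity invariant: static-window mean gravity lies on head -Z
  aligned <- apply_alignment(rec, al)
  stat <- aligned$t >= cw$static[1] + 1 & aligned$t < cw$static[2] - 1
  g <- colMeans(rec_acc(aligned)[stat, ])
  expect_lt(abs(g[1] / 9.81), 0.01)
  expect_lt(abs(g[2] / 9.81), 0.01)
  expect_lt(g[3], 0)
})

test_that("piecewise recalibration matches single alignment and recovers slippage", {
  cfg <- sim_config(seed = 8, duration_s = 300,
                    misalignment = list(axis = c(0, 1, 0), angle_deg = 5),
                    artifact_rates = list(confidence_drop_per_hour = 0,
                                          velocity_spike_per_hour = 0))
  rec <- simulate_recording(cfg)
  wl <- alignment_windows_list(attr(rec, "calibration_windows"))
  # single-window case degenerates to apply_alignment
  one <- apply_recalibrations(rec, wl[1])
  al <- estimate_alignment(rec, wl[[1]])
  expect_equal(as.data.frame(one), as.data.frame(apply_alignment(rec, al)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # no slippage: all span alignments agree
  cfg2 <- sim_config(seed = 8, duration_s = 3700,
                     misalignment = list(axis = c(0, 1, 0), angle_deg = 5),
                     artifact_rates = list(confidence_drop_per_hour = 0,
                                           velocity_spike_per_hour = 0))
  rec2 <- simulate_recording(cfg2)
  wl2 <- alignment_windows_list(attr(rec2, "calibration_windows"))
  out2 <- apply_recalibrations(rec2, wl2)
  sa <- attr(out2, "span_alignments")
  M <- rotation_from_axis_angle(c(0, 1, 0), 5)
  for (a in sa) expect_lt(rotation_angle_deg(a$R_sensor_head, M), 0.5)

  # step slippage of 5 deg about sensor X injected mid-recording: spans after
  # the next recalibration recover the new mounting within 0.5 deg
  S <- rotation_from_axis_angle(c(1, 0, 0), 5)
  M2 <- M %*% S                      # new head = M2 %*% new-sensor
  q_delta <- quat_from_matrix(t(S))  # new-sensor vectors = t(S) old-sensor
  slip <- rec2$t >= 900
  rec3 <- rec2
  qs <- rec_quat(rec2)[slip, , drop = FALSE]
  qn <- quat_normalize(quat_multiply(q_delta, qs))
  rec3$qw[slip] <- qn[, 1]; rec3$qx[slip] <- qn[, 2]
  rec3$qy[slip] <- qn[, 3]; rec3$qz[slip] <- qn[, 4]
  an <- rec_acc(rec2)[slip, , drop = FALSE] %*% S   # t(S) %*% a, row form
  wn <- rec_omega(rec2)[slip, , drop = FALSE] %*% S
  rec3$ax[slip] <- an[, 1]; rec3$ay[slip] <- an[, 2]; rec3$az[slip] <- an[, 3]
  rec3$wx[slip] <- wn[, 1]; rec3$wy[slip] <- wn[, 2]; rec3$wz[slip] <- wn[, 3]
  out3 <- apply_recalibrations(rec3, wl2)
  sa3 <- attr(out3, "span_alignments")
  breaks <- attr(out3, "span_breaks")
  post <- which(breaks >= 900)
  expect_gt(length(post), 0)
  for (k in post)
    expect_lt(rotation_angle_deg(sa3[[k]]$R_sensor_head, M2), 0.5)
})
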