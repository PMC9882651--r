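test_that("configuration invariants are enforced", {
  expect_error(sim_config(activity_transition_probs =
                            matrix(c(0.5, 0.6, 0.1, 0.9), 2, 2)),
               "row-stochastic")
  expect_error(sim_config(locomotion = list(step_freq_hz = 40)), "Nyquist")
  expect_error(sim_config(pitch_marginal = list(
    mode_deg = 0, sd_forward_deg = -1, sd_backward_deg = 1,
    tail_weight = 0)), "positive")
  expect_error(sim_config(roll_marginal = list(
    mode_deg = 0, core_sd_deg = 5, tail_sd_deg = 17, tail_weight = 1)),
    "tail_weight")
  expect_error(simulate_recording(sim_config(duration_s = 45)), "60 s")
})

test_that("fixed seeds give bit-identical recordings, different seeds differ", {
  cfg <- sim_config(seed = 11, duration_s = 90)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- simulate_recording(sim_config(seed = 12, duration_s = 90))
  expect_false(isTRUE(all.equal(r1$qw, r3$qw)))
})

test_that("stationary noise-free limit: speed ~ 0 and acceleration ~ rotated gravity", {
  cfg <- sim_config(seed = 4, duration_s = 120,
                    stationary_fraction_target = 1,
                    artifact_rates = list(confidence_drop_per_hour = 0,
                                          velocity_spike_per_hour = 0))
  rec <- simulate_recording(cfg)
  expect_lt(max(sqrt(rec$vx^2 + rec$vy^2 + rec$vz^2)), 0.75)
  resid <- rec_acc(rec) - quat_rotate(rec_quat(rec), c(0, 0, -9.81))
  expect_lt(sqrt(mean(resid^2)), 0.1)
})

test_that("recording structure is valid and segments tile the time axis", {
  rec <- default_hour_recording()
  q <- rec_quat(rec)
  expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), 1e-6)
  expect_true(all(rec$confidence %in% 0:3))
  expect_true(all(diff(rec$t) > 0))
  expect_equal(max(abs(diff(rec$t) - 1 / 62.5)), 0, tolerance = 1e-9)
  # calibration at start, every recal interval, and at the end
  expect_identical(rec$segment[1], "static_cal")
  expect_identical(rec$segment[nrow(rec)], "shake_cal")
  expect_true(any(rec$segment[rec$t >= 1800 & rec$t < 1810] == "nod_cal"))
})

test_that("gravity conservation: total minus rotated gravity is the internal inertial series", {
  rec <- default_hour_recording()
  internal <- attr(rec, "internal")
  resid <- rec_acc(rec) - quat_rotate(rec_quat(rec), c(0, 0, -9.81)) -
    internal$a_inert_sensor
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("orientation marginals and activity fractions hit the configured targets", {
  rec <- default_hour_recording()
  mask <- default_hour_mask()
  ang <- default_hour_angles()
  keep <- mask$retained
  expect_gt(sum(keep), 2e5)
  imp <- implied_orientation_moments(attr(rec, "sim_config"))
  mp <- compute_moments(ang$pitch[keep])
  mr <- compute_moments(ang$roll[keep])
  # marginals are rank-exact: agreement far inside sampling error
  expect_equal(mp$mean, imp$pitch$mean, tolerance = 0.2)
  expect_equal(mp$sd, imp$pitch$sd, tolerance = 0.2)
  expect_equal(mr$mean, imp$roll$mean, tolerance = 0.2)
  expect_equal(mr$sd, imp$roll$sd, tolerance = 0.2)
  frac_low <- retention_summary(mask, rec_rate(rec))$fraction_low
  expect_gt(frac_low, 0.90)
  expect_lt(frac_low, 0.94)
})

test_that("locomoting vertical inertial acceleration peaks at the step frequency", {
  rec <- default_hour_recording()
  mask <- default_hour_mask()
  sp <- spectra_set(rec, mask, velocity_class = "high")
  pz <- sp$P_inert[-1, "Z"]
  f <- sp$freq[-1]
  peak <- f[which.max(pz)]
  expect_lt(abs(peak - 2.0), 62.5 / 512 + 1e-9)
})

test_that("artifact injection is accounted for exactly", {
  cfg0 <- sim_config(seed = 9, duration_s = 120,
                     artifact_rates = list(confidence_drop_per_hour = 0,
                                           velocity_spike_per_hour = 0))
  rec0 <- simulate_recording(cfg0)
  art0 <- attr(rec0, "artifacts")
  expect_identical(art0$n_spikes, 0L)
  expect_identical(art0$n_confidence_epochs, 0L)

  cfg <- sim_config(seed = 9, duration_s = 1200,
                    artifact_rates = list(confidence_drop_per_hour = 40,
                                          velocity_spike_per_hour = 30))
  rec <- simulate_recording(cfg)
  art <- attr(rec, "artifacts")
  expect_gt(length(art$spike_idx), 0)
  # every injected spike exceeds the exclusion threshold
  sp <- sqrt(rec$vx^2 + rec$vy^2 + rec$vz^2)
  expect_true(all(sp[art$spike_idx] > 3.05))
  expect_true(all(sp[art$spike_idx] <= 8))
  expect_true(all(rec$confidence[art$confidence_idx] < 3))
  # rates-zero recording is untouched outside artifact indices
  base <- simulate_recording(sim_config(seed = 9, duration_s = 1200,
    artifact_rates = list(confidence_drop_per_hour = 0,
                          velocity_spike_per_hour = 0)))
  untouched <- setdiff(seq_len(nrow(rec)), art$spike_idx)
  expect_identical(rec$vx[untouched], base$vx[untouched])
  # speed filter removes exactly the spikes, nothing else
  expect_true(all(!filter_speed(rec)[art$spike_idx]))
  expect_true(all(filter_speed(rec)[untouched]))
})

test_that("written recordings read back identically", {
  rec <- simulate_recording(sim_config(seed = 2, duration_s = 90))
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_s3_class(back, "motion_recording")
  expect_equal(rec_rate(back), rec_rate(rec))
  expect_equal(back$qw, rec$qw, tolerance = 1e-12)
  expect_equal(back$vx, rec$vx, tolerance = 1e-12)
  expect_identical(back$segment, rec$segment)
})
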