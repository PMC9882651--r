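test_that("decomposition handles canonical orientations", {
  rec <- make_toy_recording(64)   # identity orientation, a_total = gravity
  d <- decompose_acceleration(rec)
  expect_equal(max(abs(d$a_inert)), 0)
  expect_equal(d$a_grav[1, ], c(0, 0, -9.81))
  # head pitched up 90 deg: gravity lies along -X (nasal-occipital)
  q <- euler_to_quat(0, 90, 0)
  rec90 <- make_toy_recording(64)
  rec90$qw <- q[1]; rec90$qx <- q[2]; rec90$qy <- q[3]; rec90$qz <- q[4]
  d90 <- decompose_acceleration(rec90)
  expect_equal(d90$a_grav[1, ], c(-9.81, 0, 0), tolerance = 1e-12)
})

test_that("decomposition is exactly additive with constant gravity norm", {
  rec <- default_hour_recording()
  d <- decompose_acceleration(rec)
  expect_lt(max(abs(d$a_grav + d$a_inert - d$a_total)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(d$a_grav^2)) - 9.81)), 1e-9)
  # round trip against the generator's internal inertial series
  expect_lt(max(abs(d$a_inert - attr(rec, "internal")$a_inert_sensor)), 1e-9)
})

test_that("Welch PSD concentrates sinusoid power and preserves variance", {
  fs <- 62.5; nfft <- 512L
  f0 <- 32 * fs / nfft
  t <- (0:(60 * fs - 1)) / fs
  x <- 3 * sin(2 * pi * f0 * t)
  p <- welch_psd(x, fs, nfft)
  expect_equal(p$freq[which.max(p$power)], f0)
  expect_equal(sum(p$power) * fs / nfft, 9 / 2, tolerance = 0.01)
  # white noise: integrated PSD equals the variance
  set.seed(2)
  xn <- rnorm(1e5, sd = 2)
  pn <- welch_psd(xn, fs, nfft)
  expect_equal(sum(pn$power) * fs / nfft, 4, tolerance = 0.05 * 4)
  expect_true(all(pn$power >= 0))
  expect_error(welch_psd(rnorm(100), fs, nfft), "no retained run")
})

test_that("masked gaps average per-segment, never across the gap", {
  set.seed(4)
  x <- rnorm(20000)
  retained <- rep(TRUE, 20000)
  retained[9001:9500] <- FALSE
  whole <- welch_psd(x, retained = retained)
  p1 <- welch_psd(x[1:9000])
  p2 <- welch_psd(x[9501:20000])
  manual <- (p1$power * p1$n_segments + p2$power * p2$n_segments) /
    (p1$n_segments + p2$n_segments)
  expect_equal(whole$power, manual, tolerance = 1e-12)
  expect_identical(whole$n_segments, p1$n_segments + p2$n_segments)
  # a short isolated run is skipped and counted
  retained2 <- rep(FALSE, 20000)
  retained2[1:5000] <- TRUE
  retained2[6001:6100] <- TRUE
  p3 <- welch_psd(x, retained = retained2)
  expect_identical(p3$n_skipped_runs, 1L)
})

test_that("crossing detector finds the analytic 1/f^2 vs constant crossing", {
  fs <- 62.5; nfft <- 512
  freqs <- (0:(nfft / 2)) * fs / nfft
  p_grav <- ifelse(freqs > 0, 1 / freqs^2, 10)
  p_inert <- rep(0.25, length(freqs))
  cr <- find_crossing(p_grav, p_inert, freqs)
  expect_true(cr$found)
  expect_lt(abs(cr$f_cross - 2), fs / nfft)
  # no crossing when gravitational power dominates everywhere
  none <- find_crossing(2 * p_inert, p_inert, freqs)
  expect_false(none$found)
  expect_true(is.na(none$f_cross))
})

test_that("crossing frequency is monotone in inertial power scaling", {
  fs <- 62.5; nfft <- 512
  freqs <- (0:(nfft / 2)) * fs / nfft
  p_grav <- ifelse(freqs > 0, 1 / freqs^2, 10)
  p_inert <- rep(0.25, length(freqs))
  f_prev <- Inf
  for (c_scale in c(0.5, 1, 2, 4, 8)) {
    cr <- find_crossing(p_grav, c_scale * p_inert, freqs)
    expect_true(cr$found)
    expect_lte(cr$f_cross, f_prev + 1e-12)
    f_prev <- cr$f_cross
  }
})

test_that("spectra_set partitions by velocity class and reports crossings", {
  rec <- default_hour_recording()
  mask <- default_hour_mask()
  sp <- spectra_set(rec, mask, "all")
  expect_identical(colnames(sp$P_grav), c("X", "Y", "Z"))
  expect_true(all(sp$P_grav >= 0) && all(sp$P_inert >= 0))
  expect_equal(range(sp$freq), c(0, 62.5 / 2))
  expect_named(sp$crossings, c("X", "Y", "Z"))
  # inertial PSDs are Parseval-consistent with their own time series:
  # integrated power equals the mean per-segment variance (mean removed per
  # segment, exactly what the estimator sees). The gravitational channel is
  # excluded here: its power sits below the resolution bandwidth, where the
  # Hann taper legitimately undercounts a within-segment trend.
  d <- decompose_acceleration(rec)
  runs <- rle(mask$retained)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (j in c(1, 3)) {
    x <- d$a_inert[, j]
    seg_var <- c()
    for (r in which(runs$values)) {
      len <- runs$lengths[r]
      if (len < 512) next
      for (o in seq(starts[r], ends[r] - 511L, by = 256L)) {
        seg <- x[o:(o + 511L)]
        seg_var <- c(seg_var, mean((seg - mean(seg))^2))
      }
    }
    integ <- sum(sp$P_inert[, j]) * 62.5 / 512
    expect_equal(integ, mean(seg_var), tolerance = 0.05 * mean(seg_var))
  }
  expect_error(spectra_set(rec, NULL, "low"), "mask")
})
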