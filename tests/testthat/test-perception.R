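test_that("likelihood sd follows the linear and shear noise laws", {
  lin <- noise_model("linear", sigma = 0.1, additive_sd = 2)
  sh <- noise_model("shear", sigma = 0.1, additive_sd = 2)
  expect_equal(likelihood_sd(0, lin), 2)
  expect_equal(likelihood_sd(0, sh), 2)
  expect_equal(likelihood_sd(30, lin), 5)
  # even in theta
  th <- seq(-120, 120, by = 7)
  expect_equal(likelihood_sd(th, sh), likelihood_sd(-th, sh))
  expect_equal(likelihood_sd(th, lin), likelihood_sd(-th, lin))
  # shear sd non-decreasing on [0, 90]; equals linear at 90 for equal sigma
  sds <- likelihood_sd(0:90, sh)
  expect_true(all(diff(sds) >= -1e-12))
  expect_equal(likelihood_sd(90, sh), likelihood_sd(90, lin))
  expect_error(noise_model("linear", sigma = -1), "non-negative")
  expect_error(noise_model("linear", sigma = 1, additive_sd = 0), "positive")
})

test_that("flat prior yields zero bias at interior angles", {
  flat <- empirical_prior(seq(-90, 90, 1), rep(1, 181))
  nm <- noise_model("linear", sigma = 0, additive_sd = 2.3)
  for (th in seq(-60, 60, by = 10))
    expect_lt(abs(posterior_bias(th, flat, nm)), 1e-9)
  curve_df <- predict_bias_curve(flat, nm, range = c(-60, 60))
  expect_lt(max(abs(curve_df$bias_deg)), 1e-9)
})

test_that("conjugate Gaussian case matches the closed form", {
  grid <- seq(-90, 90, 1)
  sp <- 10; sl <- 4
  prior <- empirical_prior(grid, dnorm(grid, 0, sp))
  nm <- noise_model("linear", sigma = 0, additive_sd = sl)
  for (th in seq(-30, 30, by = 6)) {
    expect_equal(posterior_bias(th, prior, nm),
                 -th * sl^2 / (sp^2 + sl^2), tolerance = 0.1)
  }
})

test_that("posterior is normalized and attraction/shrinkage hold", {
  grid <- seq(-90, 90, 1)
  prior <- empirical_prior(grid, dnorm(grid, 0, 12))
  nm <- noise_model("linear", sigma = 0.05, additive_sd = 3)
  for (th in c(-70, -20, 5, 40)) {
    post <- headstats:::posterior_density(th, prior, nm)
    expect_equal(sum(post) * 1, 1, tolerance = 1e-9)
  }
  # attraction: bias pulls toward the symmetric prior mode at 0
  for (th in c(-60, -25, -5, 5, 25, 60))
    expect_lt(sign(th) * posterior_bias(th, prior, nm), 0)
  # shrinkage monotonicity: wider likelihood, larger |bias|
  th <- 30
  b <- vapply(c(2, 4, 8, 16), function(a)
    abs(posterior_bias(th, prior, noise_model("linear", 0, a))), 0)
  expect_true(all(diff(b) > 0))
  # symmetric prior gives an odd bias curve
  cv <- predict_bias_curve(prior, nm, range = c(-80, 80))
  expect_equal(cv$bias_deg, -rev(cv$bias_deg), tolerance = 1e-6)
  # prior-dominant limit: enormous likelihood sd collapses onto the prior mean
  nm_wide <- noise_model("linear", sigma = 0, additive_sd = 1e4)
  prior_mean <- sum(grid * prior$density)
  expect_equal(posterior_bias(40, prior, nm_wide), prior_mean - 40,
               tolerance = 0.1)
  # underflow guard
  narrow <- empirical_prior(grid, dnorm(grid, -80, 0.25))
  expect_error(posterior_bias(80, narrow, noise_model("linear", 0, 0.5)),
               "underflow")
  expect_error(posterior_bias(200, prior, nm), "outside")
})

test_that("empirical-prior bias agrees with the fine-grid integration oracle", {
  set.seed(15)
  samp <- rsplitnorm(400, mode = 2, sd_lo = 20, sd_hi = 12)
  prior <- estimate_kde(samp, range = c(-90, 90))
  nm <- noise_model("linear", sigma = 0.08, additive_sd = 2.3)
  for (th in c(-60, -30, 10, 45)) {
    expect_equal(posterior_bias(th, prior, nm),
                 brute_posterior_bias(th, samp, prior, nm), tolerance = 0.05)
  }
})

test_that("RSE follows the n-2 definition", {
  expect_equal(rse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rse(c(1, 2, 3), c(1, 1, 1)), sqrt(5))
  r1 <- rse(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(rse(c(2, 4, 6, 8), c(0, 0, 0, 0)), 2 * r1)
  expect_error(rse(c(1, 2), c(1, 2)), "at least 3")
})

test_that("sigma fitting recovers the generating parameter", {
  prior <- default_pitch_prior()
  true_nm <- noise_model("shear", sigma = 0.10, additive_sd = 2.3)
  angles <- seq(-80, 80, by = 10)
  tab <- simulate_psych_bias(prior, true_nm, angles, obs_noise_sd_deg = 0)
  fit <- fit_tilt_perception(tab, prior, kind = "shear")
  expect_lt(abs(fit$sigma_hat - 0.10), 1e-3)
  expect_lt(fit$rse, 1e-6)
  # deterministic
  fit2 <- fit_tilt_perception(tab, prior, kind = "shear")
  expect_identical(coef(fit), coef(fit2))
  # linear kind too
  true_lin <- noise_model("linear", sigma = 0.12, additive_sd = 2.3)
  tab_lin <- simulate_psych_bias(prior, true_lin, angles, 0)
  fit_lin <- fit_tilt_perception(tab_lin, prior, kind = "linear")
  expect_lt(abs(fit_lin$sigma_hat - 0.12), 1e-3)
  # noisy recovery, small Monte Carlo (the full study is in acceptance)
  sig_hat <- vapply(1:15, function(s) {
    tb <- simulate_psych_bias(prior, true_nm, seq(-78, 78, by = 13),
                              obs_noise_sd_deg = 0.5, seed = s)
    fit_tilt_perception(tb, prior, kind = "shear")$sigma_hat
  }, 0)
  expect_lt(abs(median(sig_hat) - 0.10) / 0.10, 0.1)
})

test_that("tilt_fit behaves like a standard model object", {
  prior <- default_pitch_prior()
  nm <- noise_model("shear", sigma = 0.13, additive_sd = 2.3)
  tab <- simulate_psych_bias(prior, nm, seq(-80, 80, 20),
                             obs_noise_sd_deg = 0.4, seed = 3)
  fit <- fit_tilt_perception(tab, prior, kind = "shear")
  expect_s3_class(fit, "tilt_fit")
  expect_named(coef(fit), "sigma")
  expect_length(residuals(fit), nrow(tab))
  expect_equal(fitted(fit) + residuals(fit), tab$bias_deg)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = tab$angle_deg), fitted(fit))
  sim <- simulate(fit, nsim = 2, seed = 9, obs_noise_sd_deg = 0)
  expect_length(sim, 2)
  expect_equal(sim[[1]]$bias_deg, fitted(fit), tolerance = 1e-9)
  expect_output(print(fit), "sigma")
  expect_output(print(summary(fit)), "residuals")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
  expect_error(fit_tilt_perception(tab[1:2, ], prior), "at least 3")
})

test_that("asymmetric pitch prior biases backward pitch more than forward", {
  prior <- default_pitch_prior()
  nm <- noise_model("shear", sigma = 0.13, additive_sd = 2.3)
  cv <- predict_bias_curve(prior, nm, range = c(-85, 85))
  max_fwd <- max(abs(cv$bias_deg[cv$angle_deg < 0]))
  max_bwd <- max(abs(cv$bias_deg[cv$angle_deg > 0]))
  expect_gt(max_bwd, max_fwd)
})
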