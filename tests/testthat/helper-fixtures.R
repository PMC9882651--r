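# shared fixtures and independent oracles, built in code at test time

.fixture_env <- new.env(parent = emptyenv())

# default-configuration hour of synthetic odometry, built once per run
default_hour_recording <- function() {
  if (is.null(.fixture_env$rec_hour)) {
    .fixture_env$rec_hour <- simulate_recording(
      sim_config(seed = 1L, duration_s = 3600))
  }
  .fixture_env$rec_hour
}

default_hour_mask <- function() {
  if (is.null(.fixture_env$mask_hour)) {
    .fixture_env$mask_hour <- clean_mask(default_hour_recording())
  }
  .fixture_env$mask_hour
}

default_hour_angles <- function() {
  if (is.null(.fixture_env$ang_hour)) {
    .fixture_env$ang_hour <- angle_series(default_hour_recording(),
                                          default_hour_mask())
  }
  .fixture_env$ang_hour
}

default_pitch_prior <- function() {
  if (is.null(.fixture_env$pitch_prior)) {
    ang <- default_hour_angles()
    keep <- default_hour_mask()$retained
    .fixture_env$pitch_prior <- estimate_kde(ang$pitch[keep],
                                             range = c(-90, 90))
  }
  .fixture_env$pitch_prior
}

# minimal valid recording with prescribed channels (identity orientation)
make_toy_recording <- function(n, speeds = rep(0, n),
                               confidences = rep(3L, n),
                               segments = rep("data", n),
                               sample_rate = 62.5) {
  t <- (seq_len(n) - 1) / sample_rate
  motion_recording(data.frame(
    t = t, qw = 1, qx = 0, qy = 0, qz = 0,
    vx = speeds, vy = 0, vz = 0,
    ax = 0, ay = 0, az = -9.81,
    wx = 0, wy = 0, wz = 0,
    confidence = confidences, segment = segments,
    stringsAsFactors = FALSE), sample_rate = sample_rate)
}

# noise-free nod/shake angular-velocity series as seen by a sensor that is
# misaligned by R_m (head = R_m %*% sensor): omega_sensor = t(R_m) omega_head
make_cal_omega <- function(R_m = diag(3), noise_sd = 0, fs = 62.5,
                           duration = 10, amp = 1.1) {
  # amp 1.1 rad/s: peak angular velocity of the 20-degree, 0.5 Hz protocol
  t <- seq(0, duration, by = 1 / fs)
  base <- amp * sin(2 * pi * 0.5 * t)
  w_nod_head <- cbind(0, base, 0)
  w_shake_head <- cbind(0, 0, amp * sin(2 * pi * 0.5 * t + 0.4))
  add_noise <- function(w) w + matrix(stats::rnorm(length(w), sd = noise_sd),
                                      nrow(w), 3)
  list(nod = add_noise(w_nod_head %*% R_m),
       shake = add_noise(w_shake_head %*% R_m))
}

# definitional central-moment sums, written as explicit loops so they stay
# independent of the vectorised implementation
brute_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- m3 <- m4 <- 0
  for (xi in x) {
    d <- xi - m
    m2 <- m2 + d^2 / n
    m3 <- m3 + d^3 / n
    m4 <- m4 + d^4 / n
  }
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3)
}

# direct kernel-sum KDE oracle (scalar loops; renormalized like the package)
brute_kde <- function(x, grid, bandwidth) {
  dens <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (xi in x) s <- s + stats::dnorm(grid[i], xi, bandwidth)
    dens[i] <- s / length(x)
  }
  step <- grid[2] - grid[1]
  dens / (sum(dens) * step)
}

# fine-grid numerical-integration oracle for the posterior-mean bias:
# evaluates the same Gaussian-kernel density the prior was built from on a
# 10x finer grid and integrates the posterior there
brute_posterior_bias <- function(theta, prior_samples, prior, noise,
                                 refine = 10) {
  fine <- seq(prior$range[1], prior$range[2],
              by = prior$step / refine)
  dens <- vapply(fine, function(g)
    mean(stats::dnorm(prior_samples, g, prior$bandwidth)), 0)
  dens <- dens / (sum(dens) * (fine[2] - fine[1]))
  lik <- stats::dnorm(fine, theta, likelihood_sd(theta, noise))
  post <- dens * lik
  post <- post / sum(post)
  sum(fine * post) - theta
}

# split-normal sampler for asymmetry-ratio checks
rsplitnorm <- function(n, mode = 0, sd_lo = 1, sd_hi = 1) {
  p_lo <- sd_lo / (sd_lo + sd_hi)
  side_lo <- stats::runif(n) < p_lo
  z <- abs(stats::rnorm(n))
  ifelse(side_lo, mode - sd_lo * z, mode + sd_hi * z)
}
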