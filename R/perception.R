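#' @title Bayesian model of tilt-perception bias
#' @description A static Bayesian observer: the measured head-orientation
#'   distribution (an [empirical_prior()]) is multiplied with a Gaussian
#'   likelihood whose sd grows with eccentricity either linearly or with the
#'   sine of the tilt angle (utricular-shear geometry), and the posterior
#'   mean is the perceptual estimate. Bias is posterior mean minus true
#'   angle; a negative-toward-the-prior-mode bias is "attractive". The
#'   single free parameter sigma (the multiplicative noise on the
#'   likelihood) is fitted by minimizing the residual standard error against
#'   an observed psychophysical bias table.
#' @name perception_model
NULL

#' Likelihood noise model
#'
#' @param kind `"linear"`: sd = additive_sd + sigma * |theta|;
#'   `"shear"`: sd = additive_sd + sigma * shear_scale * |sin(theta)|.
#' @param sigma multiplicative noise parameter (>= 0).
#' @param additive_sd noise floor (deg) at 0 deg eccentricity (> 0).
#' @param shear_scale degrees applied to |sin(theta)|; the default 90 makes
#'   linear and shear sds agree at 90 deg for equal sigma, so sigma values
#'   are comparable across kinds.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("linear", "shear"), sigma,
                        additive_sd = 2.3, shear_scale = 90) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be non-negative")
  if (additive_sd <= 0) stop("additive_sd must be positive")
  structure(list(kind = kind, sigma = sigma, additive_sd = additive_sd,
                 shear_scale = shear_scale), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %s: sd(theta) = %.3f + %.4f * %s\n",
              x$kind, x$additive_sd, x$sigma,
              if (x$kind == "linear") "|theta|" else
                sprintf("%g |sin theta|", x$shear_scale)))
  invisible(x)
}

#' Eccentricity-dependent likelihood sd
#'
#' Even in theta; equals `additive_sd` at theta = 0 for both kinds.
#'
#' @param theta_deg tilt angle(s) in degrees.
#' @param noise a [noise_model()].
#' @return likelihood sd in degrees, same length as `theta_deg`.
#' @export
likelihood_sd <- function(theta_deg, noise) {
  switch(noise$kind,
         linear = noise$additive_sd + noise$sigma * abs(theta_deg),
         shear = noise$additive_sd + noise$sigma * noise$shear_scale *
           abs(sin(theta_deg * pi / 180)))
}

posterior_density <- function(theta_true, prior, noise) {
  sd <- likelihood_sd(theta_true, noise)
  lik <- stats::dnorm(prior$grid, mean = theta_true, sd = sd)
  post <- prior$density * lik
  z <- sum(post) * prior$step
  if (z < 1e-300)
    stop("posterior mass underflow; widen the prior grid or likelihood")
  post / z
}

#' Posterior-mean perception bias at one angle
#'
#' Likelihood (Gaussian centered at the true angle, sd from the noise model)
#' is evaluated on the prior grid; the posterior is the normalized pointwise
#' product and the bias is its mean minus the true angle. Negative values at
#' positive angles indicate attraction toward the prior mode.
#'
#' @param theta_true_deg true tilt angle (degrees, within the prior grid).
#' @param prior an [empirical_prior()].
#' @param noise a [noise_model()].
#' @return bias in degrees.
#' @export
posterior_bias <- function(theta_true_deg, prior, noise) {
  if (theta_true_deg < prior$range[1] || theta_true_deg > prior$range[2])
    stop("theta outside the prior grid")
  post <- posterior_density(theta_true_deg, prior, noise)
  sum(prior$grid * post) * prior$step - theta_true_deg
}

#' Predicted bias curve over the prior range
#'
#' @param prior an [empirical_prior()].
#' @param noise a [noise_model()].
#' @param range degrees `c(lo, hi)`; defaults to the prior range. Evaluated
#'   at every whole degree.
#' @return data.frame of class `bias_curve` (`angle_deg`, `bias_deg`).
#' @export
predict_bias_curve <- function(prior, noise, range = prior$range) {
  angles <- seq(ceiling(range[1]), floor(range[2]), by = 1)
  bias <- vapply(angles, posterior_bias, 0, prior = prior, noise = noise)
  structure(data.frame(angle_deg = angles, bias_deg = bias),
            class = c("bias_curve", "data.frame"))
}

#' Residual standard error of a model fit
#'
#' `sqrt(sum((y - yhat)^2) / (n - 2))`.
#'
#' @param observed,predicted numeric vectors of equal length n >= 3.
#' @return RSE in the data's units (degrees).
#' @export
rse <- function(observed, predicted) {
  n <- length(observed)
  if (n < 3L) stop("RSE needs at least 3 points (n - 2 denominator)")
  if (length(predicted) != n) stop("length mismatch")
  sqrt(sum((observed - predicted)^2) / (n - 2))
}

predicted_bias_at <- function(angles_deg, prior, noise) {
  vapply(angles_deg, posterior_bias, 0, prior = prior, noise = noise)
}

#' Fit the tilt-perception noise parameter
#'
#' Fits the single free parameter sigma of the Bayesian observer to an
#' observed bias table by minimizing the residual standard error between the
#' observed and model-predicted bias at the observed angles: a coarse search
#' over a log-spaced sigma grid (plus 0) followed by bounded scalar
#' refinement ([stats::optimize()]) around the grid minimum. Deterministic
#' for fixed inputs.
#'
#' @param observed a [psych_bias_table()] (angles at whole degrees within the
#'   prior range; n >= 3).
#' @param prior an [empirical_prior()].
#' @param kind `"linear"` or `"shear"` likelihood noise growth.
#' @param additive_sd likelihood noise floor in degrees; reported with every
#'   fit (taken from prior head-tilt modeling work, not estimated here).
#' @param bounds sigma search interval `c(lo, hi)`, `0 <= lo < hi`.
#' @param n_grid number of coarse grid points (>= 200 enforced).
#' @param shear_scale see [noise_model()].
#' @return object of class `tilt_fit` with components `sigma_hat`, `rse`,
#'   `n_points`, `kind`, `noise` (the fitted [noise_model()]), `prior`,
#'   `observed`, `fitted`, `grid` (the coarse search profile).
#' @export
fit_tilt_perception <- function(observed, prior, kind = c("linear", "shear"),
                                additive_sd = 2.3, bounds = c(0, 2),
                                n_grid = 200L, shear_scale = 90) {
  kind <- match.arg(kind)
  if (bounds[1] < 0 || bounds[2] <= bounds[1])
    stop("bounds must satisfy 0 <= lo < hi")
  if (nrow(observed) < 3L) stop("need at least 3 observed points")
  n_grid <- max(200L, n_grid)
  angles <- observed$angle_deg
  y <- observed$bias_deg
  obj <- function(sigma) {
    nm <- noise_model(kind, sigma, additive_sd, shear_scale)
    rse(y, predicted_bias_at(angles, prior, nm))
  }
  lo_pos <- max(bounds[1], 1e-4)
  sig_grid <- unique(c(0, bounds[1],
                       exp(seq(log(lo_pos), log(bounds[2]),
                               length.out = n_grid - 1L))))
  sig_grid <- sig_grid[sig_grid >= bounds[1] & sig_grid <= bounds[2]]
  prof <- vapply(sig_grid, obj, 0)
  if (any(!is.finite(prof))) stop("non-finite RSE on the sigma grid")
  i <- which.min(prof)
  lo <- sig_grid[max(1L, i - 1L)]
  hi <- sig_grid[min(length(sig_grid), i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
    if (opt$objective <= prof[i]) {
      sigma_hat <- opt$minimum; best <- opt$objective
    } else {
      sigma_hat <- sig_grid[i]; best <- prof[i]
    }
  } else {
    sigma_hat <- sig_grid[i]; best <- prof[i]
  }
  nm <- noise_model(kind, sigma_hat, additive_sd, shear_scale)
  fit <- predicted_bias_at(angles, prior, nm)
  structure(list(sigma_hat = sigma_hat, rse = best,
                 n_points = length(y), kind = kind, noise = nm,
                 additive_sd = additive_sd, prior = prior,
                 observed = observed, fitted = fit,
                 grid = data.frame(sigma = sig_grid, rse = prof),
                 call = match.call()),
            class = "tilt_fit")
}

#' @export
print.tilt_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian tilt-perception fit (%s noise)\n  sigma = %.4g, RSE = %.4g deg over %d points (additive sd %.2f deg)\n",
    x$kind, x$sigma_hat, x$rse, x$n_points, x$additive_sd))
  invisible(x)
}

#' @export
summary.tilt_fit <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(fit = object,
                 residual_range = range(res),
                 residual_rms = sqrt(mean(res^2)),
                 prior_mode = object$prior$grid[which.max(object$prior$density)]),
            class = "summary.tilt_fit")
}

#' @export
print.summary.tilt_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residuals: RMS %.3f deg, range [%.3f, %.3f]\n",
              x$residual_rms, x$residual_range[1], x$residual_range[2]))
  cat(sprintf("  prior mode at %.1f deg; likelihood sd at 0/45/90 deg: %.2f/%.2f/%.2f\n",
              x$prior_mode, likelihood_sd(0, x$fit$noise),
              likelihood_sd(45, x$fit$noise), likelihood_sd(90, x$fit$noise)))
  invisible(x)
}

#' @export
coef.tilt_fit <- function(object, ...) c(sigma = object$sigma_hat)

#' @export
fitted.tilt_fit <- function(object, ...) object$fitted

#' @export
residuals.tilt_fit <- function(object, ...)
  object$observed$bias_deg - object$fitted

#' Predict bias at new angles from a fitted tilt-perception model
#' @param object a `tilt_fit`.
#' @param newdata optional vector of angles (deg) or data.frame with
#'   `angle_deg`; default: the observed angles.
#' @param ... unused.
#' @return predicted bias (deg).
#' @export
predict.tilt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  angles <- if (is.data.frame(newdata)) newdata$angle_deg else newdata
  predicted_bias_at(angles, object$prior, object$noise)
}

#' Simulate bias tables from a fitted tilt-perception model
#' @param object a `tilt_fit`.
#' @param nsim number of tables.
#' @param seed RNG seed.
#' @param obs_noise_sd_deg observation noise sd; default the fitted RSE.
#' @param ... unused.
#' @return list of [psych_bias_table()]s.
#' @export
simulate.tilt_fit <- function(object, nsim = 1, seed = NULL,
                              obs_noise_sd_deg = object$rse, ...) {
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(k)
    simulate_psych_bias(object$prior, object$noise,
                        object$observed$angle_deg,
                        obs_noise_sd_deg, seed = seed + k - 1L))
}

#' Plot an observed bias table against the fitted bias curve
#' @param x a `tilt_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tilt_fit <- function(x, ...) {
  curve_df <- predict_bias_curve(x$prior, x$noise)
  graphics::plot(curve_df$angle_deg, curve_df$bias_deg, type = "l",
                 xlab = "true tilt (deg)", ylab = "bias (deg)",
                 main = sprintf("%s noise, sigma = %.3g", x$kind,
                                x$sigma_hat), ...)
  graphics::points(x$observed$angle_deg, x$observed$bias_deg, pch = 19)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
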