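#' @title Gravitational/inertial decomposition and power spectra
#' @description Splits head-frame total linear acceleration into its
#'   gravitational component (the world gravity vector rotated by the
#'   orientation quaternion) and the inertial remainder, estimates per-axis
#'   Welch power spectral densities over contiguous retained segments, and
#'   locates the crossing point where inertial power first exceeds
#'   gravitational power.
#' @name gravitoinertial_spectra
NULL

#' Decompose total acceleration into gravitational and inertial parts
#'
#' `a_grav(t) = R(q(t)) g_world`, `a_inert = a_total - a_grav`; the two parts
#' add back to the total exactly and `|a_grav|` equals `|g_world|` at every
#' sample by construction.
#'
#' @param rec an aligned `motion_recording`.
#' @param g_world world gravity vector (m/s^2); world Z up.
#' @return list of class `accel_decomposition` with n x 3 matrices `a_grav`,
#'   `a_inert`, `a_total` (head-frame axes X nasal-occipital, Y interaural,
#'   Z dorsal-ventral).
#' @export
decompose_acceleration <- function(rec, g_world = WORLD_GRAVITY) {
  q <- rec_quat(rec)
  nq <- sqrt(rowSums(q^2))
  if (any(abs(nq - 1) > 1e-6)) stop("non-unit quaternions in recording")
  a_grav <- quat_rotate(q / nq, g_world)
  a_total <- rec_acc(rec)
  structure(list(a_grav = a_grav, a_inert = a_total - a_grav,
                 a_total = a_total, g_world = g_world),
            class = "accel_decomposition")
}

hann_window <- function(nfft) 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))

#' Welch power spectral density over retained segments
#'
#' Contiguous runs of retained samples are split into `nfft`-sample segments
#' with 50% overlap; each segment is mean-removed, Hann-windowed and
#' periodogram-averaged. Runs shorter than `nfft` are skipped (and counted).
#' Density normalization: the integrated PSD (sum times bin width) equals the
#' signal variance, so a unit-amplitude sinusoid at a bin center carries
#' integrated power 1/2 concentrated at that bin.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param nfft FFT length (samples).
#' @param retained optional logical mask; segments never span exclusion gaps.
#' @return list of class `psd_estimate`: `freq` (Hz, 0..fs/2), `power`
#'   ((unit^2)/Hz), `n_segments`, `n_skipped_runs`.
#' @export
welch_psd <- function(x, fs = 62.5, nfft = 512L, retained = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, length(x))
  stopifnot(length(retained) == length(x))
  runs <- rle(retained)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  w <- hann_window(nfft)
  scale <- 1 / (fs * sum(w^2))
  half <- nfft %/% 2 + 1L
  acc <- numeric(half)
  n_seg <- 0L; n_skip <- 0L
  hop <- nfft %/% 2
  for (r in which(runs$values)) {
    len <- runs$lengths[r]
    if (len < nfft) { n_skip <- n_skip + 1L; next }
    offs <- seq(starts[r], ends[r] - nfft + 1L, by = hop)
    for (o in offs) {
      seg <- x[o:(o + nfft - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- abs(stats::fft(seg))^2 * scale
      p <- p[1:half]
      p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
      acc <- acc + p
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) stop("no retained run of at least nfft samples")
  structure(list(freq = (0:(half - 1L)) * fs / nfft, power = acc / n_seg,
                 n_segments = n_seg, n_skipped_runs = n_skip,
                 fs = fs, nfft = nfft),
            class = "psd_estimate")
}

#' Gravitational-to-inertial crossing point
#'
#' Both spectra (DC bin excluded) are log10-transformed and smoothed with a
#' 3-bin moving average; the crossing is the lowest frequency where the
#' inertial-minus-gravitational log-power difference changes sign from
#' negative to positive and stays positive for at least 3 consecutive bins,
#' refined by linear interpolation between the bracketing bins.
#'
#' @param p_grav,p_inert PSD vectors on a common frequency grid.
#' @param freqs frequency grid (Hz).
#' @return list of class `crossing_point`: `f_cross` (Hz, NA if none) and
#'   `found`.
#' @export
find_crossing <- function(p_grav, p_inert, freqs) {
  keep <- freqs > 0
  f <- freqs[keep]
  smooth3 <- function(v) {
    s <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  }
  d <- smooth3(log10(pmax(p_inert[keep], 1e-300))) -
    smooth3(log10(pmax(p_grav[keep], 1e-300)))
  n <- length(d)
  for (i in 2:(n - 2)) {
    if (d[i - 1] < 0 && d[i] >= 0 && all(d[i:min(n, i + 2)] > 0)) {
      f_cross <- f[i - 1] + (0 - d[i - 1]) * (f[i] - f[i - 1]) /
        (d[i] - d[i - 1])
      return(structure(list(f_cross = f_cross, found = TRUE),
                       class = "crossing_point"))
    }
  }
  structure(list(f_cross = NA_real_, found = FALSE), class = "crossing_point")
}

#' Per-axis gravitational/inertial/total spectra with crossing points
#'
#' @param rec an aligned `motion_recording`.
#' @param mask optional `clean_mask`; only retained frames enter the spectra.
#' @param velocity_class `"all"`, `"low"` or `"high"`: restrict to a velocity
#'   partition.
#' @param fs,nfft Welch parameters.
#' @param g_world world gravity vector.
#' @return list of class `spectra_set`: `freq`, matrices `P_grav`, `P_inert`,
#'   `P_total` (bins x 3 axes X/Y/Z), `crossings` (one [find_crossing()]
#'   result per axis), and segment bookkeeping.
#' @export
spectra_set <- function(rec, mask = NULL, velocity_class = c("all", "low", "high"),
                        fs = rec_rate(rec), nfft = 512L,
                        g_world = WORLD_GRAVITY) {
  velocity_class <- match.arg(velocity_class)
  retained <- if (is.null(mask)) rep(TRUE, nrow(rec)) else mask$retained
  if (velocity_class != "all") {
    if (is.null(mask)) stop("a mask is required for velocity partitioning")
    retained <- retained & !is.na(mask$velocity_class) &
      mask$velocity_class == velocity_class
  }
  dec <- decompose_acceleration(rec, g_world)
  psd3 <- function(m) {
    lapply(1:3, function(j) welch_psd(m[, j], fs, nfft, retained))
  }
  pg <- psd3(dec$a_grav); pi_ <- psd3(dec$a_inert); pt <- psd3(dec$a_total)
  freq <- pg[[1]]$freq
  P_grav <- vapply(pg, `[[`, freq, "power")
  P_inert <- vapply(pi_, `[[`, freq, "power")
  P_total <- vapply(pt, `[[`, freq, "power")
  colnames(P_grav) <- colnames(P_inert) <- colnames(P_total) <- c("X", "Y", "Z")
  crossings <- lapply(1:3, function(j)
    find_crossing(P_grav[, j], P_inert[, j], freq))
  names(crossings) <- c("X", "Y", "Z")
  structure(list(freq = freq, P_grav = P_grav, P_inert = P_inert,
                 P_total = P_total, crossings = crossings,
                 fs = fs, nfft = nfft,
                 velocity_class = velocity_class,
                 n_segments = pg[[1]]$n_segments,
                 n_skipped_runs = pg[[1]]$n_skipped_runs),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> fs %.4g Hz, nfft %d, %s velocity, %d segments\n",
              x$fs, x$nfft, x$velocity_class, x$n_segments))
  for (ax in names(x$crossings)) {
    cr <- x$crossings[[ax]]
    cat(sprintf("  %s crossing: %s\n", ax,
                if (cr$found) sprintf("%.3f Hz", cr$f_cross) else "none"))
  }
  invisible(x)
}
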