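#' Spike-train autocorrelogram
#'
#' Histogram of spike-pair lags within `window` seconds, in `bin`-second bins
#' symmetric about zero (the zero-lag bin excludes self-pairs). For theta
#' fitting the histogram is normalised to its maximum between 100 and 150 ms
#' and values above 1 are removed.
#'
#' @param spikes a `vg_spiketrain` (at least 2 spikes).
#' @param window half-width, s.
#' @param bin bin width, s.
#' @param normalize normalise for theta fitting (see above).
#' @return list of class `vg_spkac`: `lag_s` (bin centres), `count`
#'   (or normalised value; NA where values were removed), `n_spikes`.
#' @export
spike_autocorrelogram <- function(spikes, window = 0.5, bin = 0.01,
                                  normalize = TRUE) {
  s <- as.numeric(spikes)
  if (length(s) < 2) stop("need at least two spikes")
  counts <- cpp_spike_xcorr(s, window, bin)
  nb <- length(counts)
  lags <- (seq_len(nb) - (nb + 1) / 2) * bin
  counts[lags == 0] <- NA  # zero-lag bin dominated by self-structure
  if (normalize) {
    ref <- max(counts[abs(lags) >= 0.1 & abs(lags) <= 0.15], na.rm = TRUE)
    if (ref <= 0) ref <- max(counts, na.rm = TRUE)
    counts <- counts / ref
    counts[counts > 1] <- NA
  }
  structure(list(lag_s = lags, count = counts, n_spikes = length(s)),
            class = "vg_spkac")
}

#' @export
print.vg_spkac <- function(x, ...) {
  cat(sprintf("<vg_spkac> +/-%.2g s in %.0f-ms bins, %d spikes\n",
              max(x$lag_s), diff(x$lag_s[1:2]) * 1000, x$n_spikes))
  invisible(x)
}

#' Theta-modulation fit to a spike autocorrelogram
#'
#' Fits `y(t) = (a (sin(2 pi w t + pi/2) + 1) + b) exp(-|t|/tau1) +
#' c exp(-t^2/tau2^2)` to the normalised autocorrelogram by bounded
#' nonlinear least squares (L-BFGS-B with 5 deterministic multi-starts).
#' Bounds: `a, b >= 0`, `c` in [0, 0.8], `w` in [6, 12] Hz, `tau2` in
#' [0, 0.05] s; `tau1` is positive but otherwise free. The modulation
#' strength is `a / b` -- the depth of the theta-frequency oscillation in the
#' autocorrelogram relative to its baseline. Cells with fewer than
#' `min_spikes` spikes are not fitted.
#'
#' @param ac a `vg_spkac` (normalised).
#' @param min_spikes minimum spike count.
#' @return list of class `vg_thetafit`: parameters `a, b, c, omega_hz, tau1,
#'   tau2`, `modulation` (a/b), `sse`, `fitted`.
#' @export
theta_fit <- function(ac, min_spikes = 500) {
  if (ac$n_spikes < min_spikes)
    stop("fewer than ", min_spikes, " spikes: theta fit skipped")
  ok <- !is.na(ac$count)
  t <- ac$lag_s[ok]
  y <- ac$count[ok]
  model <- function(p, t) {
    (p[1] * (sin(2 * pi * p[4] * t + pi / 2) + 1) + p[2]) *
      exp(-abs(t) / p[5]) + p[3] * exp(-t^2 / p[6]^2)
  }
  sse <- function(p) sum((model(p, t) - y)^2)
  lower <- c(0, 0, 0, 6, 1e-3, 1e-4)
  upper <- c(Inf, Inf, 0.8, 12, Inf, 0.05)
  starts <- list(c(0.2, 0.5, 0, 8, 0.1, 0.02),
                 c(0.5, 0.2, 0, 7, 0.2, 0.01),
                 c(0.1, 0.8, 0.1, 9, 0.05, 0.03),
                 c(0.3, 0.3, 0, 10.5, 0.15, 0.02),
                 c(0.4, 0.6, 0.2, 6.5, 0.3, 0.04))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, sse, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("theta fit failed to converge")
  p <- best$par
  structure(list(a = p[1], b = p[2], c = p[3], omega_hz = p[4],
                 tau1 = p[5], tau2 = p[6],
                 modulation = p[1] / p[2], sse = best$value,
                 fitted = model(p, ac$lag_s)),
            class = "vg_thetafit")
}

#' @export
print.vg_thetafit <- function(x, ...) {
  cat(sprintf(
    "<vg_thetafit> omega %.2f Hz, a/b %.3f (a %.3f b %.3f c %.3f), sse %.3f\n",
    x$omega_hz, x$modulation, x$a, x$b, x$c, x$sse))
  invisible(x)
}

#' Simulate a theta-modulated (or homogeneous) Poisson spike train
#'
#' Inhomogeneous Poisson with rate
#' `base_hz * (1 + depth * cos(2 pi f t))`, thinned at 1 kHz resolution.
#' `depth = 0` gives a homogeneous train. Used as ground truth for
#' [theta_fit()] recovery.
#'
#' @param duration s.
#' @param base_hz mean rate.
#' @param f_hz modulation frequency.
#' @param depth modulation depth in [0, 1].
#' @param seed RNG seed.
#' @return a [spiketrain()].
#' @export
simulate_theta_train <- function(duration, base_hz = 10, f_hz = 8,
                                 depth = 0.8, seed = 1) {
  with_seed(seed, {
    dt <- 1e-3
    n <- round(duration / dt)
    tt <- (seq_len(n) - 0.5) * dt
    lam <- base_hz * (1 + depth * cos(2 * pi * f_hz * tt)) * dt
    keep <- runif(n) < lam
    spiketrain(tt[keep] + runif(sum(keep), -dt / 2, dt / 2), "theta_sim")
  })
}

#' Speed-rate tuning and linear fit
#'
#' Instantaneous firing rate is the spike histogram in 20-ms bins smoothed
#' with a 13-bin (260 ms) Gaussian window; running speed is interpolated to
#' the same bins, binned in 2 cm/s increments, and the mean rate per speed
#' bin is fitted with a least-squares line. Empty speed bins are excluded.
#'
#' @param traj,spikes session data.
#' @param speed_bin speed bin width, cm/s.
#' @param rate_bin instantaneous-rate bin, s.
#' @param smooth_bins Gaussian window length in rate bins.
#' @param max_speed speeds above this are ignored, cm/s.
#' @return list of class `vg_speedfit`: `bin_centers`, `mean_rate_hz`,
#'   `time_s`, `slope`, `intercept`, `sse`.
#' @export
speed_rate_score <- function(traj, spikes, speed_bin = 2, rate_bin = 0.02,
                             smooth_bins = 13, max_speed = 60) {
  t0 <- min(traj$t)
  t1 <- max(traj$t)
  edges <- seq(t0, t1, by = rate_bin)
  if (length(edges) < smooth_bins + 2) stop("session too short")
  counts <- tabulate(findInterval(as.numeric(spikes), edges,
                                  all.inside = TRUE),
                     nbins = length(edges) - 1)
  k <- gauss_kernel(smooth_bins / 6, radius = (smooth_bins - 1) / 2)
  inst <- as.numeric(stats::filter(counts / rate_bin, k, sides = 2))
  mid <- edges[-length(edges)] + rate_bin / 2
  spd <- approx(traj$t, traj$speed, xout = mid, rule = 2)$y
  ok <- !is.na(inst) & spd <= max_speed
  sb <- floor(spd[ok] / speed_bin)
  rate <- tapply(inst[ok], sb, mean)
  time_s <- tapply(inst[ok], sb, length) * rate_bin
  centers <- (as.numeric(names(rate)) + 0.5) * speed_bin
  if (length(centers) < 2) stop("single occupied speed bin: fit undefined")
  fit <- lm(rate ~ centers)
  structure(list(bin_centers = centers, mean_rate_hz = as.numeric(rate),
                 time_s = as.numeric(time_s),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 sse = sum(fit$residuals^2)),
            class = "vg_speedfit")
}

#' @export
print.vg_speedfit <- function(x, ...) {
  cat(sprintf(
    "<vg_speedfit> slope %.3f Hz/(cm/s), intercept %.2f Hz, %d bins\n",
    x$slope, x$intercept, length(x$bin_centers)))
  invisible(x)
}
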