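#' Spatial information and sparsity of a rate map
#'
#' Skaggs information in both conventions, with occupancy probabilities
#' `p_i`, per-voxel rates `lambda_i` and mean rate `lambda = sum(p_i
#' lambda_i)`:
#' rate form `sum p_i lambda_i log2(lambda_i / lambda)` (bits/s) and
#' per-spike form `sum p_i (lambda_i / lambda) log2(lambda_i / lambda)`
#' (bits/spike); they satisfy `bits_s = lambda * bits_spike`. Sparsity is
#' `(sum p_i lambda_i)^2 / sum p_i lambda_i^2`, 1 for a uniform map and
#' smaller the more firing concentrates.
#'
#' @param map a [ratemap3d] (typically a 2 cm histogram map smoothed with a
#'   2-voxel Gaussian), or a plain rate array with an `occupancy` attribute.
#' @return list of class `vg_info`: `spatial_info_rate` (bits/s),
#'   `spatial_info_spike` (bits/spike), `sparsity`, `mean_rate_hz`.
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "vg_ratemap"))
  ok <- map$visited & !is.na(map$rate)
  occ <- map$occupancy
  if (is.null(occ)) stop("occupancy required for spatial information")
  p <- occ[ok] / sum(occ[ok])
  lam <- map$rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) {
    return(structure(list(spatial_info_rate = 0, spatial_info_spike = 0,
                          sparsity = NA_real_, mean_rate_hz = 0),
                     class = "vg_info"))
  }
  pos <- lam > 0
  lg <- log2(lam[pos] / lbar)
  info_rate <- sum(p[pos] * lam[pos] * lg)
  info_spike <- sum(p[pos] * (lam[pos] / lbar) * lg)
  sparsity <- lbar^2 / sum(p * lam^2)
  structure(list(spatial_info_rate = info_rate,
                 spatial_info_spike = info_spike,
                 sparsity = sparsity, mean_rate_hz = lbar),
            class = "vg_info")
}

#' @export
print.vg_info <- function(x, ...) {
  cat(sprintf(
    "<vg_info> %.3f bits/s, %.3f bits/spike, sparsity %.3f, mean %.3f Hz\n",
    x$spatial_info_rate, x$spatial_info_spike, x$sparsity, x$mean_rate_hz))
  invisible(x)
}

#' Circular spike-shift shuffle of a statistic
#'
#' Recomputes `statistic` on `n` circularly shifted copies of the spike train
#' (shift uniform between `min_shift` and `T - min_shift`, on an `increment`
#' grid) and standardises the observed value:
#' `z = (observed - mean(shuffle)) / sd(shuffle)`. Values above 1.96 exceed
#' the shuffle at the 0.05 level.
#'
#' @param traj,spikes session data.
#' @param statistic `function(traj, spikes) -> numeric(1)`.
#' @param n shuffles.
#' @param increment shift granularity, s.
#' @param min_shift minimum shift, s.
#' @param seed RNG seed.
#' @return list of class `vg_shuffle`: `observed`, `z`, `mu`, `sigma`,
#'   `values`.
#' @export
spike_shift_shuffle <- function(traj, spikes, statistic, n = 100,
                                increment = 0.02, min_shift = 20,
                                seed = NULL) {
  t_range <- range(traj$t)
  T <- diff(t_range)
  if (T <= 2 * min_shift) stop("session too short for circular shifts")
  obs <- statistic(traj, spikes)
  values <- with_seed(seed, {
    vapply(seq_len(n), function(k) {
      shift <- round(runif(1, min_shift, T - min_shift) / increment) *
        increment
      v <- tryCatch(statistic(traj, circular_shift(spikes, shift, t_range)),
                    error = function(e) NA_real_)
      as.numeric(v)
    }, numeric(1))
  })
  mu <- mean(values, na.rm = TRUE)
  sigma <- sd(values, na.rm = TRUE)
  structure(list(observed = obs, z = (obs - mu) / sigma, mu = mu,
                 sigma = sigma, values = values),
            class = "vg_shuffle")
}

#' @export
print.vg_shuffle <- function(x, ...) {
  cat(sprintf("<vg_shuffle> observed %.4f, shuffle %.4f +/- %.4f, z = %.2f\n",
              x$observed, x$mu, x$sigma, x$z))
  invisible(x)
}

#' Split-half stability of a spatial map
#'
#' Splits the session into its first and second halves (by time), builds a
#' map per half, and correlates them (Pearson) over mutually visited bins.
#' Volumetric maps use 10 cm voxels with a 2.5-bin Gaussian; planar variants
#' project onto a coordinate plane with 2.5 cm bins and a 1-bin Gaussian.
#'
#' @param traj,spikes session data (speed filtered).
#' @param map_kind `"volumetric"` or `"planar"`.
#' @param plane projection plane for the planar variant.
#' @param environment a `vg_environment`.
#' @return list `r`, `n_bins`, `maps` (the two half maps).
#' @export
split_half_stability <- function(traj, spikes,
                                 map_kind = c("volumetric", "planar"),
                                 plane = "XY", environment = NULL) {
  map_kind <- match.arg(map_kind)
  environment <- environment %||% traj_env(traj)
  t_mid <- (min(traj$t) + max(traj$t)) / 2
  halves <- lapply(list(traj$t <= t_mid, traj$t > t_mid), function(sel) {
    tr <- traj[sel, , drop = FALSE]
    attr(tr, "environment") <- environment
    class(tr) <- class(traj)
    sp <- spiketrain(as.numeric(spikes)[
      (as.numeric(spikes) <= t_mid) == sel[1]])
    if (!length(sp)) stop("one half has no spikes: stability undefined")
    if (map_kind == "volumetric") {
      histogram_ratemap(tr, sp, bin_cm = 10, smooth_sd = 2.5,
                        environment = environment)
    } else {
      m <- histogram_ratemap(tr, sp, bin_cm = 2.5, smooth_sd = 1,
                             environment = environment,
                             flatten = environment$size_cm[3] <= 0)
      if (dims3(m$rate)[3] > 1) project_ratemap(m, plane) else m
    }
  })
  a <- halves[[1]]$rate
  b <- halves[[2]]$rate
  ok <- !is.na(a) & !is.na(b) & halves[[1]]$visited & halves[[2]]$visited
  r <- if (sum(ok) >= 3 && stats::var(a[ok]) > 0 && stats::var(b[ok]) > 0)
    cor(a[ok], b[ok]) else NA_real_
  list(r = r, n_bins = sum(ok), maps = halves)
}

#' Null distribution for map stability from mismatched cell pairs
#'
#' Correlates half-session maps drawn from *different* cells (first half of
#' one against second half of another), building the chance distribution the
#' observed split-half correlations are compared with.
#'
#' @param half_maps list of `list(first, second)` map pairs, one per cell.
#' @param n_pairs shuffled pairs to draw.
#' @param seed RNG seed.
#' @return numeric vector of null correlations.
#' @export
stability_null <- function(half_maps, n_pairs = 5000, seed = 1) {
  nc <- length(half_maps)
  stopifnot(nc >= 2)
  with_seed(seed, {
    vapply(seq_len(n_pairs), function(k) {
      ij <- sample(nc, 2)
      a <- half_maps[[ij[1]]]$first$rate
      b <- half_maps[[ij[2]]]$second$rate
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3 || stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0)
        return(NA_real_)
      cor(a[ok], b[ok])
    }, numeric(1))
  })
}

#' Directional (azimuthal head-direction) tuning curve
#'
#' Bins time and spikes by projected movement azimuth into 6-degree bins,
#' smooths both histograms with a circular Gaussian (`sigma = 3` bins), and
#' divides to get the tuning curve. Reports the Rayleigh vector length of
#' the curve and the preferred direction (bin of maximum rate).
#'
#' @param traj,spikes session data.
#' @param bin_deg directional bin width.
#' @param smooth_sd circular smoothing, bins.
#' @param sample_rate tracking rate, Hz.
#' @return list of class `vg_dirtuning`: `bin_centers_deg`, `rate_hz`,
#'   `rayleigh`, `preferred_deg`, `n_spikes`, `low_n`.
#' @export
directional_tuning <- function(traj, spikes, bin_deg = 6, smooth_sd = 3,
                               sample_rate = 25) {
  nb <- as.integer(round(360 / bin_deg))
  az <- (traj$azimuth * 180 / pi) %% 360
  bin_of <- function(deg) pmin(pmax(ceiling(deg / bin_deg), 1L), nb)
  occ <- tabulate(bin_of(az), nb) / sample_rate
  spk_az <- approx(traj$t, az, xout = as.numeric(spikes), rule = 2)$y
  spk <- tabulate(bin_of(spk_az), nb)
  occ_s <- circ_smooth(occ, smooth_sd)
  spk_s <- circ_smooth(spk, smooth_sd)
  rate <- ifelse(occ_s > 0, spk_s / occ_s, 0)
  th <- (seq_len(nb) - 0.5) * bin_deg * pi / 180
  w <- sum(rate)
  rayleigh <- if (w > 0) Mod(sum(rate * exp(1i * th))) / w else 0
  structure(list(bin_centers_deg = (seq_len(nb) - 0.5) * bin_deg,
                 rate_hz = rate, rayleigh = rayleigh,
                 preferred_deg = (which.max(rate) - 0.5) * bin_deg,
                 n_spikes = length(spikes), low_n = length(spikes) < 100),
            class = "vg_dirtuning")
}

#' @export
print.vg_dirtuning <- function(x, ...) {
  cat(sprintf(
    "<vg_dirtuning> Rayleigh %.3f, preferred %.0f deg, %d spikes%s\n",
    x$rayleigh, x$preferred_deg, x$n_spikes,
    if (x$low_n) " (low n)" else ""))
  invisible(x)
}

#' Population stability of directional tuning across environments
#'
#' Pools every cell's arena tuning curve against its lattice curve and
#' correlates the two pooled vectors. The null independently circularly
#' shifts each lattice curve by a random number of bins (1..nbins) and
#' recomputes the pooled correlation `n` times; the population is stable
#' when the observed correlation exceeds the null's 95th percentile. A
#' z-score of the observed value against the null is also reported.
#'
#' @param arena_curves,lattice_curves lists of tuning-curve vectors (same
#'   cells, same bin count).
#' @param n null repetitions.
#' @param seed RNG seed.
#' @return list `r`, `z`, `significant`, `null`.
#' @export
directional_population_stability <- function(arena_curves, lattice_curves,
                                             n = 1000, seed = 1) {
  stopifnot(length(arena_curves) == length(lattice_curves))
  a <- unlist(arena_curves)
  b <- unlist(lattice_curves)
  r <- cor(a, b)
  null <- with_seed(seed, {
    vapply(seq_len(n), function(k) {
      shifted <- lapply(lattice_curves, function(v) {
        s <- sample.int(length(v), 1)
        v[((seq_along(v) - 1 + s) %% length(v)) + 1]
      })
      cor(a, unlist(shifted))
    }, numeric(1))
  })
  z <- (r - mean(null)) / sd(null)
  list(r = r, z = z, significant = r > quantile(null, 0.95, names = FALSE),
       null = null)
}
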