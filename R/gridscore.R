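#' Hexagonal and square gridness scores of a 2D autocorrelogram
#'
#' The autocorrelogram is thresholded (values > `threshold`), the seven most
#' central correlation peaks (8-connected components, nearest centroids to the
#' centre) are found, the central peak is excluded, and the annulus containing
#' the remaining six peaks is isolated: inner/outer radii are the mean peak
#' ring radius minus/plus the central-peak radius. Pearson correlations
#' between the annulus and rotated copies of itself (bilinear sampling) give
#' the scores: HGS = min(corr at 60, 120) - max(corr at 30, 90, 150) and
#' SGS = min(corr at 90, 180) - max(corr at 45, 135, 225). High HGS means
#' sixfold (hexagonal), high SGS fourfold (square) symmetry.
#'
#' @param ac2d a `vg_autocorr` with a singleton third dimension, or a numeric
#'   matrix of correlations (NA allowed).
#' @param threshold correlation threshold for peak detection.
#' @param min_pixels minimum annulus pixel pairs per rotation.
#' @return object of class `vg_gridscore`: list with `hgs`, `sgs` (NA when the
#'   cell is unscorable), `scorable`, `reason`, `annulus_inner`,
#'   `annulus_outer` (pixels), `peak_centers` and `rot_corr` (correlation at
#'   each rotation used).
#' @export
grid_score <- function(ac2d, threshold = 0.3, min_pixels = 20) {
  a <- if (inherits(ac2d, "vg_autocorr")) ac2d$r[, , 1] else as.matrix(ac2d)
  d <- dim(a)
  ctr <- (d + 1) / 2
  unscorable <- function(why)
    structure(list(hgs = NA_real_, sgs = NA_real_, scorable = FALSE,
                   reason = why, annulus_inner = NA, annulus_outer = NA,
                   peak_centers = NULL, rot_corr = NULL),
              class = "vg_gridscore")
  mask <- !is.na(a) & a > threshold
  if (!any(mask)) return(unscorable("no super-threshold values"))
  lab <- array(cpp_label(as.logical(mask), dims3(mask), 26L), dim = d)
  cen <- component_centroids(array(lab, dim = c(d, 1L)))[, 1:2, drop = FALSE]
  if (nrow(cen) < 7) return(unscorable("fewer than 7 peaks"))
  dist <- sqrt((cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2)
  ord <- order(dist)[1:7]
  central_id <- ord[which.min(dist[ord])]
  ring_ids <- setdiff(ord, central_id)
  r_central <- sqrt(sum(lab == central_id) / pi)
  ring <- mean(dist[ring_ids])
  inner <- max(0, ring - r_central)
  outer <- ring + r_central

  geom <- cached_grid_geom(d)
  px <- geom$px
  ann <- which(px >= inner & px <= outer & !is.na(a))
  if (length(ann) < min_pixels) return(unscorable("annulus too small"))
  ax <- geom$co[ann, 1] - ctr[1]
  ay <- geom$co[ann, 2] - ctr[2]
  base <- a[ann]
  angles <- c(30, 45, 60, 90, 120, 135, 150, 180, 225)
  rc <- vapply(angles, function(phi) {
    th <- phi * pi / 180
    rx <- cos(th) * ax - sin(th) * ay + ctr[1]
    ry <- sin(th) * ax + cos(th) * ay + ctr[2]
    rot <- cpp_interp3(a, dims3(a), rx, ry, rep(1, length(rx)))
    ok <- !is.na(rot)
    if (sum(ok) < min_pixels) return(NA_real_)
    if (stats::var(base[ok]) < 1e-14 || stats::var(rot[ok]) < 1e-14)
      return(NA_real_)
    cor(base[ok], rot[ok])
  }, numeric(1))
  names(rc) <- paste0("deg", angles)
  hgs <- min(rc["deg60"], rc["deg120"]) -
    max(rc["deg30"], rc["deg90"], rc["deg150"])
  sgs <- min(rc["deg90"], rc["deg180"]) -
    max(rc["deg45"], rc["deg135"], rc["deg225"])
  structure(list(hgs = unname(hgs), sgs = unname(sgs), scorable = TRUE,
                 reason = NULL, annulus_inner = inner, annulus_outer = outer,
                 peak_centers = cen[ord, , drop = FALSE], rot_corr = rc),
            class = "vg_gridscore")
}

#' @rdname grid_score
#' @export
hgs <- function(ac2d, ...) grid_score(ac2d, ...)$hgs

#' @rdname grid_score
#' @param ... passed to `grid_score`.
#' @export
sgs <- function(ac2d, ...) grid_score(ac2d, ...)$sgs

#' @export
print.vg_gridscore <- function(x, ...) {
  if (!x$scorable)
    cat(sprintf("<vg_gridscore> unscorable (%s)\n", x$reason))
  else
    cat(sprintf("<vg_gridscore> HGS = %.3f, SGS = %.3f (annulus %.1f-%.1f px)\n",
                x$hgs, x$sgs, x$annulus_inner, x$annulus_outer))
  invisible(x)
}

#' Circularly shift a spike train within the session
#'
#' @param spikes a `vg_spiketrain`.
#' @param shift shift, s.
#' @param t_range session bounds (defaults to spike range).
#' @return shifted `vg_spiketrain`.
#' @export
circular_shift <- function(spikes, shift, t_range = NULL) {
  s <- as.numeric(spikes)
  t_range <- t_range %||% range(s)
  T <- diff(t_range)
  spiketrain(((s - t_range[1] + shift) %% T) + t_range[1],
             cell_id = attr(spikes, "cell_id"))
}

#' Bootstrap-versus-shuffle significance of a spatial statistic
#'
#' The statistic is first estimated as the median over `n` bootstrap
#' resamples of the spike train (spikes drawn with replacement), then compared
#' with a null distribution of `n` values obtained by circularly shifting the
#' spike train by at least `min_shift` seconds (uniform over the admissible
#' range, on an `increment`-second grid) and recomputing the statistic. The
#' statistic is deemed greater than chance when the bootstrap median exceeds
#' the 95th percentile of the shuffle distribution. If the statistic fails
#' (returns NA) on more than half of either set, significance is undefined.
#'
#' @param traj a `vg_trajectory`.
#' @param spikes a `vg_spiketrain`.
#' @param statistic `function(traj, spikes) -> numeric(1)`.
#' @param n iterations per arm.
#' @param min_shift minimum circular shift, s.
#' @param increment shift granularity, s.
#' @param seed RNG seed.
#' @return object of class `vg_shuffle_sig`: `bootstrap_median`,
#'   `shuffle_values`, `percentile_95`, `significant`.
#' @export
bootstrap_vs_shuffle <- function(traj, spikes, statistic, n = 100,
                                 min_shift = 20, increment = 0.02,
                                 seed = NULL) {
  t_range <- range(traj$t)
  T <- diff(t_range)
  if (T <= 2 * min_shift) stop("session too short for circular shifts")
  s <- as.numeric(spikes)
  eval_stat <- function(sp) {
    v <- tryCatch(statistic(traj, sp), error = function(e) NA_real_)
    if (length(v) != 1) NA_real_ else as.numeric(v)
  }
  res <- with_seed(seed, {
    boot <- vapply(seq_len(n), function(i) {
      eval_stat(spiketrain(sample(s, length(s), replace = TRUE)))
    }, numeric(1))
    shuf <- vapply(seq_len(n), function(i) {
      shift <- round(runif(1, min_shift, T - min_shift) / increment) * increment
      eval_stat(circular_shift(spikes, shift, t_range))
    }, numeric(1))
    list(boot = boot, shuf = shuf)
  })
  if (mean(is.na(res$boot)) > 0.5 || mean(is.na(res$shuf)) > 0.5) {
    return(structure(list(bootstrap_median = NA_real_,
                          shuffle_values = res$shuf, percentile_95 = NA_real_,
                          significant = NA), class = "vg_shuffle_sig"))
  }
  bm <- median(res$boot, na.rm = TRUE)
  p95 <- quantile(res$shuf, 0.95, na.rm = TRUE, names = FALSE)
  structure(list(bootstrap_median = bm, shuffle_values = res$shuf,
                 percentile_95 = p95, significant = bm > p95),
            class = "vg_shuffle_sig")
}

#' @export
print.vg_shuffle_sig <- function(x, ...) {
  cat(sprintf(
    "<vg_shuffle_sig> bootstrap median %.3f vs shuffle 95th pct %.3f: %s\n",
    x$bootstrap_median, x$percentile_95,
    if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Grid-cell inclusion criterion
#'
#' A cell qualifies as a grid cell when its hexagonal gridness score exceeds
#' chance (bootstrap-versus-shuffle) in *both* arena sessions recorded before
#' and after the volumetric session.
#'
#' @param sig_arena1,sig_arena2 `vg_shuffle_sig` results for the two sessions.
#' @return logical.
#' @export
grid_cell_criterion <- function(sig_arena1, sig_arena2) {
  isTRUE(sig_arena1$significant) && isTRUE(sig_arena2$significant)
}

#' Gridness-score statistic factory for shuffle testing
#'
#' Builds a `statistic(traj, spikes)` closure that speed-filters the data,
#' builds an adaptive rate map, autocorrelates it and returns the HGS (or
#' SGS), for use with [bootstrap_vs_shuffle()].
#'
#' @param score `"hgs"` or `"sgs"`.
#' @param voxel_cm,alpha adaptive-map parameters.
#' @param environment a `vg_environment` (defaults to the trajectory's).
#' @param min_speed speed filter, cm/s.
#' @export
gridness_statistic <- function(score = c("hgs", "sgs"), voxel_cm = 2.5,
                               alpha = 1600, environment = NULL,
                               min_speed = 5) {
  score <- match.arg(score)
  function(traj, spikes) {
    sf <- speed_filter(traj, spikes, min_speed)
    m <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = voxel_cm,
                          alpha = alpha, environment = environment)
    ac <- autocorrelation(m)
    gs <- grid_score(ac)
    if (score == "hgs") gs$hgs else gs$sgs
  }
}
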