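#' Spatial autocorrelation of a firing-rate map
#'
#' Pearson-normalised spatial autocorrelation at every integer-voxel lag,
#' computed over the overlapping *visited* voxels of the map and its shifted
#' copy (unvisited voxels are excluded pairwise, never zero-filled). Lags with
#' fewer than `min_overlap` contributing voxel pairs are undefined. The result
#' has side `2n - 1` per axis, `r = 1` at zero lag and `r(tau) = r(-tau)`.
#'
#' @param map a [ratemap3d], or a 2D/3D numeric array (NA = unvisited).
#' @param min_overlap minimum number of voxel pairs per lag.
#' @param method `"direct"` evaluates the masked sums lag by lag; `"fft"`
#'   computes the same sums by zero-padded FFT cross-correlations (identical
#'   result up to floating-point rounding, much faster on large volumes);
#'   `"auto"` switches to FFT above 20,000 voxels.
#' @return object of class `vg_autocorr`: list with `r` (lag array), `m`
#'   (overlap counts), `lag_voxel_cm` and `center` (index of the zero lag).
#' @export
autocorrelation <- function(map, min_overlap = 20,
                            method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  voxel <- 1
  if (inherits(map, "vg_ratemap")) {
    voxel <- map$voxel_cm
    a <- map$rate
    a[!map$visited] <- NA
  } else a <- map
  d <- dims3(a)
  if (length(dim(a)) < 3) dim(a) <- d
  vals <- a[!is.na(a)]
  if (length(vals) < 2) stop("need at least two visited voxels")
  if (stats::var(vals) < 1e-14) stop("constant map: autocorrelation undefined")
  if (method == "auto")
    method <- if (prod(d) > 20000) "fft" else "direct"
  if (method == "fft") {
    res <- masked_autocorr_fft(a, min_overlap)
  } else {
    raw <- cpp_autocorr(as.numeric(a), d, as.integer(min_overlap))
    ld <- 2L * d - 1L
    ld[d == 1L] <- 1L
    res <- list(r = array(raw$r, dim = ld), m = array(raw$m, dim = ld))
  }
  structure(list(r = res$r, m = res$m, lag_voxel_cm = voxel, center = d),
            class = "vg_autocorr")
}

# Masked per-lag Pearson autocorrelation via FFT cross-correlations of the
# zero-filled values, their squares and the visited mask; exactly the same
# sums as the direct evaluation, up to floating-point rounding.
masked_autocorr_fft <- function(a, min_overlap) {
  d <- dims3(a)
  ld <- ifelse(d == 1L, 1L, 2L * d - 1L)
  w <- array(as.numeric(!is.na(a)), dim = d)
  a0 <- a
  a0[is.na(a0)] <- 0
  pad <- function(x) {
    p <- array(0, dim = ld)
    p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    p
  }
  rev3 <- function(x) {
    idx <- lapply(d, function(n) rev(seq_len(n)))
    x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  xc <- function(Fg, Frh) Re(fft(Fg * Frh, inverse = TRUE)) / prod(ld)
  Fa <- fft(pad(a0)); Fa2 <- fft(pad(a0^2)); Fw <- fft(pad(w))
  Far <- fft(pad(rev3(a0))); Fa2r <- fft(pad(rev3(a0^2)))
  Fwr <- fft(pad(rev3(w)))
  M <- round(xc(Fw, Fwr))
  Sa <- xc(Fa, Fwr); Sb <- xc(Fw, Far)
  Saa <- xc(Fa2, Fwr); Sbb <- xc(Fw, Fa2r)
  Sab <- xc(Fa, Far)
  va <- M * Saa - Sa^2
  vb <- M * Sbb - Sb^2
  scale2 <- max(Saa) ^ 2
  ok <- M >= min_overlap & va > 1e-9 * scale2 & vb > 1e-9 * scale2
  r <- array(NA_real_, dim = ld)
  r[ok] <- (M[ok] * Sab[ok] - Sa[ok] * Sb[ok]) / sqrt(va[ok] * vb[ok])
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  list(r = r, m = array(as.integer(M), dim = ld))
}

#' @export
print.vg_autocorr <- function(x, ...) {
  cat(sprintf("<vg_autocorr> %s lags of %.3g cm, %.0f%% defined\n",
              paste(dim(x$r), collapse = "x"), x$lag_voxel_cm,
              100 * mean(!is.na(x$r))))
  invisible(x)
}

# connected component (26-connectivity) of super-threshold lags containing the
# zero lag; returns a logical array
central_region <- function(ac, threshold = 0.25) {
  mask <- !is.na(ac$r) & ac$r > threshold
  if (!mask[ac$center[1], ac$center[2], ac$center[3]])
    stop("no central peak above threshold")
  lab <- array(cpp_label(as.logical(mask), dims3(mask), 26L), dim = dim(mask))
  lab == lab[ac$center[1], ac$center[2], ac$center[3]]
}

#' Correct an autocorrelation for field anisotropy
#'
#' Extracts the central super-threshold region of the autocorrelogram (which
#' mirrors the average field shape) and rescales the volume along each axis so
#' that this region's axis extents become equal, turning elongated fields --
#' and with them, anisotropically stretched close-packed arrangements -- back
#' into spheres before planar-symmetry scoring. Resampling is trilinear on an
#' unchanged cubic-voxel grid; per-axis scale factors are limited to [0.5, 2].
#'
#' @param ac a `vg_autocorr`.
#' @param threshold correlation threshold defining the central region.
#' @return a corrected `vg_autocorr`.
#' @export
anisotropy_correct <- function(ac, threshold = 0.25) {
  reg <- central_region(ac, threshold)
  idx <- which(reg, arr.ind = TRUE)
  ext <- apply(idx, 2, function(i) diff(range(i)) + 1)
  d <- dim(ac$r)
  flat <- d == 1L
  touches <- vapply(which(!flat), function(ax)
    any(idx[, ax] == 1L | idx[, ax] == d[ax]), logical(1))
  if (length(touches) && all(touches))
    warning("central region touches volume faces; correction limited")
  target <- exp(mean(log(ext[!flat])))
  scale <- ifelse(flat, 1, pmin(2, pmax(0.5, ext / target)))
  ctr <- ac$center
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  src <- sweep(sweep(g, 2, ctr), 2, scale, `*`)
  src <- sweep(src, 2, ctr, `+`)
  vals <- cpp_interp3(ac$r, dims3(ac$r), src[, 1], src[, 2], src[, 3])
  out <- ac
  out$r <- array(vals, dim = d)
  out$meta_scale <- scale
  out
}

#' Field radius from the autocorrelation central peak
#'
#' The radius of a sphere whose volume equals that of the thresholded central
#' autocorrelation region -- an average field-size estimate that does not
#' depend on field detection.
#'
#' @param ac a `vg_autocorr`.
#' @param threshold correlation threshold.
#' @return radius in cm.
#' @export
central_peak_radius <- function(ac, threshold = 0.25) {
  reg <- central_region(ac, threshold)
  v <- sum(reg)
  if (dim(ac$r)[3] == 1L) sqrt(v / pi) * ac$lag_voxel_cm
  else (3 * v / (4 * pi))^(1 / 3) * ac$lag_voxel_cm
}

#' Grid spacing by the expanding-sphere estimator
#'
#' A sphere is expanded from the autocorrelation centre in 1-bin steps up to
#' 0.6x the maximum side length; at each radius the median correlation within
#' 2 bins of the sphere surface is recorded. The spacing is the first local
#' maximum of this shell profile after the central peak (prominence at least
#' `min_prominence`, radius at least `min_radius` bins). Cells without a
#' qualifying peak get `NA` spacing (recorded, not an error).
#'
#' @param ac a `vg_autocorr`.
#' @param shell_halfwidth half-thickness of the shell, bins.
#' @param min_prominence,min_radius peak acceptance rules.
#' @return list of class `vg_spacing`: `d` (cm, or NA), `shell_profile`
#'   (data frame radius_bins/median_r), `peak_prominence`.
#' @export
grid_spacing <- function(ac, shell_halfwidth = 2, min_prominence = 0.01,
                         min_radius = 5) {
  d <- dim(ac$r)
  ctr <- ac$center
  co <- arrayInd(seq_along(ac$r), d)
  dist <- sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                 (co[, 3] - ctr[3])^2)
  rmax <- floor(0.6 * max(d))
  prof <- vapply(seq_len(rmax), function(r) {
    sel <- abs(dist - r) <= shell_halfwidth
    v <- ac$r[sel]
    v <- v[!is.na(v)]
    if (length(v) < 10) NA_real_ else median(v)
  }, numeric(1))
  pk <- find_peaks(prof, min_prominence = min_prominence,
                   min_index = min_radius)
  est <- if (length(pk)) pk[1] * ac$lag_voxel_cm else NA_real_
  prom <- if (length(pk)) {
    p <- pk[1]
    prof[p] - min(prof[seq_len(p)], na.rm = TRUE)
  } else NA_real_
  structure(list(d = est,
                 shell_profile = data.frame(radius_bins = seq_len(rmax),
                                            median_r = prof),
                 peak_prominence = prom),
            class = "vg_spacing")
}

#' @export
print.vg_spacing <- function(x, ...) {
  cat(sprintf("<vg_spacing> d = %s cm\n",
              if (is.na(x$d)) "undefined" else format(x$d, digits = 4)))
  invisible(x)
}

#' Autocorrelation midline profiles
#'
#' The correlation values along the three axis-aligned lines through the
#' autocorrelation centre. A columnar map gives a flat, high z-midline and
#' peaked x/y midlines; a compact field arrangement gives three peaked
#' profiles.
#'
#' @param ac a `vg_autocorr`.
#' @return list of numeric vectors `x`, `y`, `z` (lag index along each axis).
#' @export
midline_profiles <- function(ac) {
  ctr <- ac$center
  list(x = ac$r[, ctr[2], ctr[3]],
       y = ac$r[ctr[1], , ctr[3]],
       z = ac$r[ctr[1], ctr[2], ])
}

#' Vertical self-similarity of a volumetric rate map
#'
#' Pearson correlation of the map with vertically shifted copies of itself,
#' computed over the overlapping, mutually visited voxels. In a close-packed
#' arrangement with spacing `d`, layers repeat every `0.816 d` of height, so
#' the profile shows structure at multiples of `0.816 d`: HCP repeats its
#' identical layer at shift `2 x 0.816 d`, FCC at `3 x 0.816 d`, while
#' columnar maps stay near 1 at every shift.
#'
#' @param map a [ratemap3d].
#' @param d grid spacing, cm (e.g. from [grid_spacing()]).
#' @param min_overlap minimum voxel pairs per shift.
#' @return data frame with `shift_cm`, `shift_d` (shift in units of d) and
#'   `r`, with attribute `peaks` (shift_d of local maxima).
#' @export
vertical_self_similarity <- function(map, d, min_overlap = 100) {
  if (is.na(d) || d <= 0) stop("grid spacing d is undefined")
  a <- map$rate
  a[!map$visited] <- NA
  nz <- dim(a)[3]
  r <- vapply(0:(nz - 2), function(k) {
    top <- a[, , (k + 1):nz, drop = FALSE]
    bot <- a[, , 1:(nz - k), drop = FALSE]
    ok <- !is.na(top) & !is.na(bot)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (stats::var(top[ok]) < 1e-14 || stats::var(bot[ok]) < 1e-14)
      return(NA_real_)
    cor(top[ok], bot[ok])
  }, numeric(1))
  shift_cm <- (0:(nz - 2)) * map$voxel_cm
  out <- data.frame(shift_cm = shift_cm, shift_d = shift_cm / d, r = r)
  pk <- find_peaks(r, min_prominence = 0.01, min_index = 2)
  attr(out, "peaks") <- out$shift_d[pk]
  out
}
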