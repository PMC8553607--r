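#' @useDynLib volgrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd quantile cor rnorm runif rpois approx optim
#'   complete.cases fft coef lm dist var
#' @importFrom utils head tail read.table write.table
NULL

# Deterministic derivation of per-operation seeds from a master seed.
# Keeps results below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 11 * k) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

dims3 <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  as.integer(c(d, rep(1L, 3 - length(d)))[1:3])
}

# Separable Gaussian smoothing of a 2D/3D array. NA handling: values are
# smoothed with mask normalisation (NA treated as missing, not zero), and NA
# cells stay NA unless fill = TRUE.
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

smooth_axis <- function(a, axis, kernel) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  # banded smoothing matrix with renormalised edges (kernel clipped at borders)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kernel[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  sm <- K %*% m
  out <- array(sm, dim = d[perm])
  aperm(out, order(perm))
}

gauss_smooth <- function(a, sigma, na_mask = TRUE) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  k <- gauss_kernel(sigma)
  nas <- is.na(a)
  if (any(nas)) {
    w <- array(as.numeric(!nas), dim = d)
    a0 <- a
    a0[nas] <- 0
    for (ax in seq_along(d)) if (d[ax] > 1) {
      a0 <- smooth_axis(a0, ax, k)
      w <- smooth_axis(w, ax, k)
    }
    out <- a0 / w
    out[w <= 0] <- NA
    if (na_mask) out[nas] <- NA
    out
  } else {
    out <- a
    for (ax in seq_along(d)) if (d[ax] > 1) out <- smooth_axis(out, ax, k)
    out
  }
}

# circular smoothing of a vector (used for directional tuning curves)
circ_smooth <- function(x, sigma) {
  n <- length(x)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  xp <- c(tail(x, r), x, head(x, r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
}

# 26-neighbourhood maximum filter via shifted pmax (separable box maximum)
max_filter <- function(a) {
  d <- dim(a)
  out <- a
  for (ax in seq_along(d)) {
    if (d[ax] <= 1) next
    lo <- hi <- out
    idx_lo <- lapply(d, seq_len)
    idx_hi <- idx_lo
    idx_lo[[ax]] <- c(1L, seq_len(d[ax] - 1L))
    idx_hi[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    lo <- do.call(`[`, c(list(out), idx_lo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(out), idx_hi, list(drop = FALSE)))
    out <- pmax(out, lo, hi)
  }
  out
}

# Morphological reconstruction by dilation of `marker` under `mask`
# (marker <= mask), then regional maxima of the H-maxima transform.
morph_reconstruct <- function(marker, mask, max_iter = 10000L) {
  g <- marker
  for (i in seq_len(max_iter)) {
    g2 <- pmin(max_filter(g), mask)
    if (isTRUE(all.equal(g2, g, tolerance = 1e-12))) break
    g <- g2
  }
  g
}

# Regional maxima of the H-maxima transform of `a` (NA treated as -Inf):
# connected plateaus from which every descending path drops by more than h.
h_maxima <- function(a, h, connectivity = 26L) {
  b <- a
  b[is.na(b)] <- -Inf
  rec <- morph_reconstruct(b - h, b)
  em <- (b - rec) >= h - 1e-9
  lab <- array(cpp_label(as.logical(em), dims3(em), as.integer(connectivity)),
               dim = dim(a))
  lab
}

component_centroids <- function(lab) {
  d <- dims3(lab)
  w <- which(lab > 0)
  if (!length(w)) return(matrix(numeric(0), 0, 3))
  co <- arrayInd(w, d)
  g <- lab[w]
  s <- rowsum(cbind(co, 1), g)
  s[, 1:3, drop = FALSE] / s[, 4]
}

# per-dims geometry cache (voxel coordinates and centre distances)
.vg_cache <- new.env(parent = emptyenv())

cached_grid_geom <- function(d) {
  key <- paste(d, collapse = "x")
  g <- .vg_cache[[key]]
  if (is.null(g)) {
    co <- arrayInd(seq_len(prod(d)), d)
    ctr <- (d + 1) / 2
    px <- sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                 (if (length(d) > 2) (co[, 3] - ctr[3])^2 else 0))
    g <- list(co = co, px = px, ctr = ctr)
    .vg_cache[[key]] <- g
  }
  g
}

# First local maximum by prominence in a 1D profile (positions are indices in
# `x`); prominence = height above the higher of the two flanking minima.
find_peaks <- function(y, min_prominence = 0, min_index = 1L) {
  n <- length(y)
  if (n < 3) return(integer(0))
  pk <- which(diff(sign(diff(y))) < 0) + 1L
  pk <- pk[!is.na(y[pk]) & pk >= min_index]
  keep <- logical(length(pk))
  for (i in seq_along(pk)) {
    p <- pk[i]
    # prominence: drop to the highest of the two flanking minima, where each
    # flank extends to the nearest strictly higher sample (or the profile end)
    lb <- suppressWarnings(max(which(y[seq_len(p - 1)] > y[p])))
    rb <- if (p < n) suppressWarnings(min(which(y[(p + 1):n] > y[p]) + p)) else Inf
    lmin <- min(y[(if (is.finite(lb)) lb else 1):p], na.rm = TRUE)
    rmin <- min(y[p:(if (is.finite(rb)) rb else n)], na.rm = TRUE)
    keep[i] <- (y[p] - max(lmin, rmin)) >= min_prominence
  }
  pk[keep]
}

# Rotation matrix for a rotation by `angle_deg` about unit axis `axis`
# (Rodrigues form).
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Resample a 3D array after rotating it about its centre. pad = 0 gives
# zero-padding outside the original volume, pad = NA leaves values undefined.
rotate_volume <- function(a, axis, angle_deg, pad = 0) {
  d <- dim(a)
  R <- rotation_matrix(axis, angle_deg)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  src <- t(t(g) - ctr) %*% R  # inverse map: R^T applied as right-multiplication
  src <- t(t(src) + ctr)
  vals <- cpp_interp3(a, dims3(a), src[, 1], src[, 2], src[, 3])
  out <- array(vals, dim = d)
  if (!is.na(pad)) out[is.na(out) ] <- pad
  out
}

# direction vector of a plane normal given pitch (deg, from +z) and azimuth
sph_dir <- function(pitch_deg, azimuth_deg) {
  p <- pitch_deg * pi / 180
  a <- azimuth_deg * pi / 180
  cbind(sin(p) * cos(a), sin(p) * sin(a), cos(p))
}

# minimal circular difference between two angle sets (degrees, period `per`)
circ_diff <- function(a, b, per = 360) {
  d <- (a - b) %% per
  pmin(d, per - d)
}

# Distance from point(s) p (rows) to the convex hull of rows of X, by
# Frank-Wolfe minimisation of |Xw - p|^2 over the simplex, run jointly for
# all query points. Used for hull membership and Monte-Carlo convex volumes.
hull_distance <- function(p, X, iter = 120L) {
  p <- rbind(p)
  X <- as.matrix(X)
  xw <- matrix(colMeans(X), nrow(p), 3, byrow = TRUE)
  for (k in seq_len(iter)) {
    s <- max.col(-((xw - p) %*% t(X)), ties.method = "first")
    gamma <- 2 / (k + 2)
    xw <- (1 - gamma) * xw + gamma * X[s, , drop = FALSE]
  }
  sqrt(rowSums((xw - p)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
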