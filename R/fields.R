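#' Detect 3D firing fields in an adaptive rate map
#'
#' Fields are 26-connected regions of voxels above `threshold` (fraction of
#' the map peak) that contain more than `min_voxels` voxels, reach a peak rate
#' above `min_peak_hz`, and were visited more than `min_visits` times. A visit
#' is a maximal run of consecutive trajectory samples inside the field's
#' voxels; runs separated by at least 1 s count separately.
#'
#' @param map a [ratemap3d] (2.5 cm adaptive maps in the reference analysis).
#' @param traj the session trajectory (used for visit counting; `NULL` skips
#'   the visit criterion).
#' @param threshold field threshold as a fraction of the map peak.
#' @param min_voxels minimum contiguous voxels.
#' @param min_peak_hz minimum in-field peak rate, Hz.
#' @param min_visits minimum number of visits.
#' @return object of class `vg_fieldset`: a data frame with one row per field
#'   (centroid `x, y, z` in cm, `volume_cm3`, `peak_hz`, `n_voxels`, `visits`,
#'   principal axis lengths `p1 >= p2 >= p3`, `elongation`) plus attributes
#'   `voxels` (list of voxel-index matrices), `eigvec` (list of 3x3
#'   orientation matrices, columns = axes) and `map_dim`.
#' @export
detect_fields <- function(map, traj = NULL, threshold = 0.30,
                          min_voxels = 64, min_peak_hz = 1,
                          min_visits = 5) {
  a <- map$rate
  a[!map$visited] <- NA
  pk <- suppressWarnings(max(a, na.rm = TRUE))
  empty <- structure(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               volume_cm3 = numeric(0), peak_hz = numeric(0),
               n_voxels = integer(0), visits = integer(0), p1 = numeric(0),
               p2 = numeric(0), p3 = numeric(0), elongation = numeric(0)),
    voxels = list(), eigvec = list(), map_dim = dim(a), voxel_cm = map$voxel_cm,
    class = c("vg_fieldset", "data.frame"))
  if (!is.finite(pk) || pk <= 0) return(empty)
  mask <- !is.na(a) & a > threshold * pk
  lab <- array(cpp_label(as.logical(mask), dims3(mask), 26L), dim = dim(a))
  ids <- seq_len(max(lab))
  if (!length(ids)) return(empty)

  traj_idx <- if (!is.null(traj)) {
    d <- dims3(a)
    bin_index(cbind(traj$x, traj$y, traj$z), map$voxel_cm, d, map$origin_cm)
  }
  rows <- list()
  voxl <- list()
  eigl <- list()
  for (id in ids) {
    w <- which(lab == id)
    if (length(w) <= min_voxels) next
    peak <- max(a[w])
    if (peak <= min_peak_hz) next
    co <- arrayInd(w, dims3(a))
    visits <- NA_integer_
    if (!is.null(traj)) {
      dd <- dims3(a)
      lin_f <- co[, 1] + dd[1] * (co[, 2] - 1) + prod(dd[1:2]) * (co[, 3] - 1)
      lin_t <- traj_idx[, 1] + dd[1] * (traj_idx[, 2] - 1) +
        prod(dd[1:2]) * (traj_idx[, 3] - 1)
      visits <- count_visits(traj$t, lin_t %in% lin_f)
      if (visits <= min_visits) next
    }
    ax <- field_axes_voxels(co)
    cen <- (colMeans(co) - 0.5) * map$voxel_cm + map$origin_cm
    rows[[length(rows) + 1]] <- data.frame(
      x = cen[1], y = cen[2], z = cen[3],
      volume_cm3 = length(w) * map$voxel_cm^3, peak_hz = peak,
      n_voxels = length(w), visits = visits,
      p1 = ax$lengths[1] * map$voxel_cm, p2 = ax$lengths[2] * map$voxel_cm,
      p3 = ax$lengths[3] * map$voxel_cm,
      elongation = ax$lengths[1] / (0.5 * (ax$lengths[2] + ax$lengths[3])))
    voxl[[length(voxl) + 1]] <- co
    eigl[[length(eigl) + 1]] <- ax$vectors
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, voxels = voxl, eigvec = eigl, map_dim = dim(a),
            voxel_cm = map$voxel_cm,
            class = c("vg_fieldset", "data.frame"))
}

# maximal runs of TRUE separated by >= 1 s count as separate visits
count_visits <- function(t, inside, min_gap = 1) {
  if (!any(inside)) return(0L)
  w <- which(inside)
  breaks <- which(diff(t[w]) >= min_gap)
  length(breaks) + 1L
}

#' Principal axes of a voxelised field region
#'
#' Eigen-decomposition of the second central moments of the voxel
#' coordinates, matching the normalized-second-moment ellipsoid convention: a
#' 1/12 voxel term accounts for voxel extent, and axis lengths are
#' `2 * sqrt(5 * eigenvalue)` (the solid ellipsoid with those moments). Axes
#' are sorted in descending length.
#'
#' @param field_voxels n x 3 matrix of voxel indices.
#' @return list `lengths` (voxel units, descending) and `vectors`
#'   (orthonormal columns).
#' @export
field_axes_voxels <- function(field_voxels) {
  co <- as.matrix(field_voxels)
  if (nrow(co) < 2) stop("field too small for axis estimation")
  cc <- sweep(co, 2, colMeans(co))
  cv <- crossprod(cc) / nrow(co) + diag(3) / 12
  e <- eigen(cv, symmetric = TRUE)
  list(lengths = 2 * sqrt(5 * pmax(e$values, 0)), vectors = e$vectors)
}

#' Elongation index of a field
#'
#' In 3D the ratio of the largest principal axis to the mean of the other
#' two, `P1 / (0.5 * (P2 + P3))`; in 2D simply `P1 / P2`. 1 for a sphere;
#' larger values mean elongation.
#'
#' @param p principal-axis lengths, descending.
#' @param dims 3 (volumetric) or 2 (planar arena maps).
#' @return numeric elongation index, >= 1 for ideal inputs.
#' @export
elongation_index <- function(p, dims = 3) {
  if (dims == 2) p[1] / p[2] else p[1] / (0.5 * (p[2] + p[3]))
}

#' Equivalent diameter of a field from its convex volume
#'
#' Diameter of the sphere with the same volume as the field's convex hull:
#' `(6 vf / pi)^(1/3)`.
#'
#' @param vf convex volume, cm^3.
#' @return diameter, cm.
#' @export
equivalent_diameter <- function(vf) (6 * vf / pi)^(1 / 3)

#' Convex volume of a field (Monte-Carlo estimate)
#'
#' Volume of the convex hull of the field's voxels (the hull of the voxel
#' centres dilated by half a voxel, matching the voxelised convex-image
#' convention), estimated by seeded uniform sampling of the bounding box with
#' a Frank-Wolfe distance-to-hull membership test (precision a few percent).
#'
#' @param field_voxels n x 3 voxel-index matrix.
#' @param voxel_cm voxel size.
#' @param n_samples Monte-Carlo samples.
#' @param seed RNG seed.
#' @return volume, cm^3.
#' @export
convex_volume <- function(field_voxels, voxel_cm = 1, n_samples = 4000,
                          seed = 1) {
  co <- as.matrix(field_voxels)
  box_lo <- apply(co, 2, min) - 0.5
  box_hi <- apply(co, 2, max) + 0.5
  vol_box <- prod(box_hi - box_lo)
  pts <- with_seed(seed, matrix(runif(3 * n_samples), n_samples, 3))
  pts <- sweep(sweep(pts, 2, box_hi - box_lo, `*`), 2, box_lo, `+`)
  dd <- hull_distance(pts, co, iter = 120L)
  mean(dd < 0.5) * vol_box * voxel_cm^3
}

#' Elongation significance by spherical-field respray
#'
#' Tests whether a field is more elongated than expected from an underlying
#' spherical field sampled through the actual trajectory. The field's in-field
#' spikes are resprayed `n` times from an isotropic Gaussian centred on the
#' field centroid whose s.d. matches the field's equivalent radius through
#' the 20%-threshold relation (radius = 1.8 sigma), assigned to the nearest
#' trajectory point; the rate map is rebuilt from the resprayed spikes, the
#' field re-extracted, and its elongation collected. The observed elongation
#' is z-scored against this null.
#' `z > 1.96` flags the field as nonspherical.
#'
#' @param fields a `vg_fieldset`; the test runs on field `index`.
#' @param index field row to test.
#' @param traj,spikes session data (speed filtered).
#' @param map the adaptive [ratemap3d] the fields came from.
#' @param n resprays.
#' @param seed RNG seed.
#' @return list `elongation`, `z`, `nonspherical`, `shuffle` (vector),
#'   `equivalent_diameter_cm`.
#' @export
elongation_shuffle <- function(fields, index, traj, spikes, map, n = 100,
                               seed = 1) {
  vox <- attr(fields, "voxels")[[index]]
  cen <- as.numeric(fields[index, c("x", "y", "z")])
  d <- dims3(map$rate)
  lin_f <- vox[, 1] + d[1] * (vox[, 2] - 1) + prod(d[1:2]) * (vox[, 3] - 1)
  spk_pos <- position_at(traj, as.numeric(spikes))
  spk_idx <- bin_index(spk_pos, map$voxel_cm, d, map$origin_cm)
  lin_s <- spk_idx[, 1] + d[1] * (spk_idx[, 2] - 1) +
    prod(d[1:2]) * (spk_idx[, 3] - 1)
  in_field <- lin_s %in% lin_f
  n_spk <- sum(in_field)
  if (n_spk == 0) stop("no in-field spikes")

  vf <- convex_volume(vox, map$voxel_cm, seed = derive_seed(seed, 1))
  eq_d <- equivalent_diameter(vf)
  # a Gaussian field thresholded at 20% of peak extends to ~1.8 sigma
  # (sqrt(2 log 5) = 1.79), so a respray that should re-create a field of
  # this radius needs sigma = radius / 1.8
  sd_cm <- (eq_d / 2) / 1.8
  tp <- cbind(traj$x, traj$y, traj$z)
  near_cen <- which(sqrt((tp[, 1] - cen[1])^2 + (tp[, 2] - cen[2])^2 +
                           (tp[, 3] - cen[3])^2) <= 3 * sd_cm)
  if (length(near_cen) < 10) near_cen <- seq_len(nrow(tp))
  cand <- tp[near_cen, , drop = FALSE]

  # occupancy is fixed; each respray rebuilds the adaptive map from the
  # resprayed in-field spikes and re-extracts the field's elongation exactly
  # as the observed path did
  occ <- count_array(bin_index(tp, map$voxel_cm, d, map$origin_cm), d)
  max_r <- as.integer(ceiling(sqrt(sum(d^2)) / 2))
  cen_vox <- bin_index(rbind(cen), map$voxel_cm, d, map$origin_cm)
  respray_elong <- function(pos) {
    spk <- count_array(bin_index(pos, map$voxel_cm, d, map$origin_cm), d)
    res <- cpp_adaptive(as.numeric(occ), as.numeric(spk), d,
                        map$alpha %||% 1600, max_r, map$sample_rate)
    r <- array(res$rate, dim = d)
    pk <- max(r, na.rm = TRUE)
    if (!is.finite(pk) || pk <= 0) return(NA_real_)
    mask <- !is.na(r) & r > 0.3 * pk
    lab <- array(cpp_label(as.logical(mask), d, 26L), dim = d)
    id <- lab[cen_vox[1], cen_vox[2], cen_vox[3]]
    if (id == 0) {
      cents <- component_centroids(lab)
      if (!nrow(cents)) return(NA_real_)
      id <- which.min(rowSums(sweep(cents, 2, as.numeric(cen_vox))^2))
    }
    w <- which(lab == id)
    if (length(w) < 4) return(NA_real_)
    ax <- tryCatch(field_axes_voxels(arrayInd(w, d)), error = function(e) NULL)
    if (is.null(ax)) return(NA_real_)
    elongation_index(ax$lengths)
  }
  shuffle_elong <- with_seed(derive_seed(seed, 2), {
    vapply(seq_len(n), function(k) {
      g <- matrix(rnorm(3 * n_spk, mean = rep(cen, each = n_spk),
                        sd = sd_cm), n_spk, 3)
      nn <- vapply(seq_len(n_spk), function(i) {
        which.min((cand[, 1] - g[i, 1])^2 + (cand[, 2] - g[i, 2])^2 +
                    (cand[, 3] - g[i, 3])^2)
      }, 1L)
      respray_elong(cand[nn, , drop = FALSE])
    }, numeric(1))
  })
  obs <- fields$elongation[index]
  mu <- mean(shuffle_elong, na.rm = TRUE)
  sdv <- sd(shuffle_elong, na.rm = TRUE)
  z <- (obs - mu) / sdv
  list(elongation = obs, z = z, nonspherical = z > 1.96,
       shuffle = shuffle_elong, equivalent_diameter_cm = eq_d)
}

#' Field-orientation axis test
#'
#' Projects each field's principal axis (and its antipode) onto the unit
#' sphere and counts fields whose axis lies within a 30-degree half-angle cap
#' of each Cartesian axis (two opposing caps per axis, together ~13.4% of the
#' sphere). Chance bands come from `n_mc` draws of `n_fields` uniform axes;
#' an axis is flagged when the observed proportion falls outside the
#' 2.5th-97.5th percentile band.
#'
#' @param fields a `vg_fieldset` (or an n x 3 matrix of unit axis vectors).
#' @param n_mc Monte-Carlo repetitions.
#' @param half_angle cap half-angle, degrees.
#' @param seed RNG seed.
#' @return data frame with one row per Cartesian axis: `count`, `proportion`,
#'   `chance_lo`, `chance_hi`, `flagged`.
#' @export
orientation_axis_test <- function(fields, n_mc = 1000, half_angle = 30,
                                  seed = 1) {
  vecs <- if (is.matrix(fields)) fields
          else t(vapply(attr(fields, "eigvec"), function(e) e[, 1],
                        numeric(3)))
  nf <- nrow(vecs)
  stopifnot(nf >= 1)
  cth <- cos(half_angle * pi / 180)
  counts <- colSums(abs(vecs) > cth)  # |axis . e_k| > cos(30) for either cap
  props <- counts / nf
  chance <- with_seed(seed, {
    vapply(seq_len(n_mc), function(k) {
      u <- matrix(rnorm(3 * nf), nf, 3)
      u <- u / sqrt(rowSums(u^2))
      colSums(abs(u) > cth) / nf
    }, numeric(3))
  })
  lo <- apply(chance, 1, quantile, 0.025)
  hi <- apply(chance, 1, quantile, 0.975)
  data.frame(axis = c("x", "y", "z"), count = counts, proportion = props,
             chance_lo = lo, chance_hi = hi,
             flagged = props < lo | props > hi)
}

#' Spherical kernel density of orientation vectors
#'
#' Density at each grid point on the unit sphere as the sum of Gaussian
#' weights `exp(-0.5 (x / sigma)^2)` of the great-circle angles `x` (degrees)
#' to every datum -- a von Mises-Fisher-style smoothed density for
#' visualising field orientations.
#'
#' @param vectors n x 3 matrix of unit vectors.
#' @param sigma kernel s.d., degrees.
#' @param n_grid sphere grid resolution (n_grid x n_grid).
#' @return list `dirs` (grid directions), `density`, `phi`, `theta`.
#' @export
vmf_density <- function(vectors, sigma = 10, n_grid = 60) {
  stopifnot(nrow(vectors) >= 1)
  theta <- seq(0, 180, length.out = n_grid)
  phi <- seq(0, 360, length.out = n_grid + 1)[seq_len(n_grid)]
  g <- expand.grid(p = phi, t = theta)
  dirs <- cbind(sin(g$t * pi / 180) * cos(g$p * pi / 180),
                sin(g$t * pi / 180) * sin(g$p * pi / 180),
                cos(g$t * pi / 180))
  dots <- dirs %*% t(vectors)
  dots[] <- pmin(1, pmax(-1, dots))
  ang <- acos(dots) * 180 / pi
  dens <- rowSums(exp(-0.5 * (ang / sigma)^2))
  list(dirs = dirs, density = dens, phi = g$p, theta = g$t)
}

#' Field-position shuffle of a rate map
#'
#' Randomises field positions while preserving each field's internal
#' structure and the map's value distribution. The map is oversmoothed
#' (Gaussian `sigma_bins`), field peaks are found as H-maxima (`h`) regional
#' maxima, and every visited voxel is assigned to its nearest peak (the
#' watershed of the peak distance transform). Each field's peak bin then
#' moves to a random visited position, and remaining bins follow field by
#' field (cycled in order), each placed at its ideal offset from the new peak
#' or, if taken, the nearest free visited bin in city-block distance.
#' Unvisited bins keep their positions; the value multiset, the peak rate and
#' the unvisited mask are preserved exactly.
#'
#' @param map a [ratemap3d].
#' @param seed RNG seed.
#' @param sigma_bins oversmoothing width.
#' @param h H-maxima depth.
#' @return a [ratemap3d] with shuffled field positions (meta `field_labels`
#'   holds the watershed provenance).
#' @export
field_shuffle <- function(map, seed = 1, sigma_bins = 3, h = 0.2) {
  a <- map$rate
  a[!map$visited] <- NA
  sm <- gauss_smooth(a, sigma_bins)
  labs <- h_maxima(sm, h)
  peaks <- component_centroids(labs)
  if (nrow(peaks) == 0) return(map)
  d <- dims3(a)
  visited <- which(!is.na(a))
  co_v <- arrayInd(visited, d)
  # nearest-peak (Voronoi) segmentation of visited voxels
  dmat <- vapply(seq_len(nrow(peaks)), function(k) {
    (co_v[, 1] - peaks[k, 1])^2 + (co_v[, 2] - peaks[k, 2])^2 +
      (co_v[, 3] - peaks[k, 3])^2
  }, numeric(nrow(co_v)))
  seg <- max.col(-dmat, ties.method = "first")
  nf <- nrow(peaks)
  # peak bin per field = highest-rate bin in the segment
  old_peaks <- vapply(seq_len(nf), function(k) {
    w <- visited[seg == k]
    w[which.max(a[w])]
  }, 1L)
  field_bins <- lapply(seq_len(nf), function(k) {
    w <- visited[seg == k]
    w <- setdiff(w, old_peaks[k])
    if (!length(w)) return(integer(0))
    po <- arrayInd(old_peaks[k], d)
    cw <- arrayInd(w, d)
    dd <- (cw[, 1] - po[1])^2 + (cw[, 2] - po[2])^2 + (cw[, 3] - po[3])^2
    w[order(dd)]
  })
  new_peaks <- with_seed(seed, sample(visited, nf))
  shuffled <- cpp_field_shuffle(as.numeric(a), d, field_bins,
                                as.integer(old_peaks),
                                as.integer(new_peaks))
  out <- map
  out$rate <- array(shuffled, dim = d)
  out$meta$field_labels <- {
    fl <- array(0L, dim = d)
    fl[visited] <- seg
    fl
  }
  out
}

#' Local order of grid fields: interfield-distance CV
#'
#' Builds a histogram map (2 cm voxels, 2.5-bin Gaussian), thresholds at 10%
#' of peak, takes H-maxima (`h = 0.8`) regional maxima as field centroids,
#' iteratively merges centroids closer than 25 cm, and computes the CV
#' (sd/mean) of the deduplicated 3-nearest-neighbour distances. The null
#' repeats the measurement on circularly shifted spike trains, accepting only
#' shuffles whose field count is within +/-3 of the observed count (up to
#' `max_attempts`, targeting `n_target` accepted shuffles).
#'
#' @param traj,spikes session data (speed filtered).
#' @param bin_cm,smooth_sd map parameters.
#' @param h H-maxima depth, Hz.
#' @param merge_cm centroid merge radius.
#' @param n_target accepted shuffles wanted; 0 skips the null.
#' @param max_attempts shuffle attempts allowed.
#' @param environment a `vg_environment`.
#' @param seed RNG seed.
#' @return list `cv`, `n_fields`, `centroids`, `shuffle_cvs`,
#'   `shuffle_mean`, `comparison` (`"more ordered"` when cv < shuffle mean).
#' @export
interfield_cv <- function(traj, spikes, bin_cm = 2, smooth_sd = 2.5,
                          h = 0.8, merge_cm = 25, n_target = 100,
                          max_attempts = 1000, environment = NULL,
                          seed = 1) {
  environment <- environment %||% traj_env(traj)
  one_cv <- function(sp) {
    m <- histogram_ratemap(traj, sp, bin_cm = bin_cm, smooth_sd = smooth_sd,
                           environment = environment)
    cen <- field_centroids_hmax(m, h = h, peak_frac = 0.1,
                                merge_cm = merge_cm)
    list(cv = interfield_distance_cv(cen), n = nrow(cen))
  }
  obs <- one_cv(spikes)
  shuffle_cvs <- numeric(0)
  if (n_target > 0 && !is.na(obs$cv)) {
    t_range <- range(traj$t)
    T <- diff(t_range)
    shuffle_cvs <- with_seed(seed, {
      out <- numeric(0)
      for (k in seq_len(max_attempts)) {
        if (length(out) >= n_target) break
        shift <- round(runif(1, 20, T - 20) / 0.2) * 0.2
        res <- one_cv(circular_shift(spikes, shift, t_range))
        if (!is.na(res$cv) && abs(res$n - obs$n) <= 3)
          out <- c(out, res$cv)
      }
      out
    })
  }
  list(cv = obs$cv, n_fields = obs$n,
       shuffle_cvs = shuffle_cvs,
       shuffle_mean = if (length(shuffle_cvs)) mean(shuffle_cvs) else NA_real_,
       comparison = if (length(shuffle_cvs)) {
         if (obs$cv < mean(shuffle_cvs)) "more ordered" else "not more ordered"
       } else NA_character_)
}

#' CV of deduplicated 3-nearest-neighbour interfield distances
#'
#' For each centroid the distances to its three nearest neighbours are
#' collected, repeated distances are discarded, and the coefficient of
#' variation (sd/mean) of the remainder is returned. Near-zero CV means the
#' fields sit on a locally regular lattice. `NA` with fewer than two
#' centroids or fewer than two distinct distances.
#'
#' @param centroids n x 3 matrix, cm.
#' @return numeric CV.
#' @export
interfield_distance_cv <- function(centroids) {
  if (is.null(nrow(centroids)) || nrow(centroids) < 2) return(NA_real_)
  dd <- as.matrix(dist(centroids))
  diag(dd) <- Inf
  nn3 <- apply(dd, 1, function(r) sort(r)[seq_len(min(3, length(r) - 1))])
  dists <- unique(round(as.numeric(nn3), 9))
  if (length(dists) < 2) return(0)
  sd(dists) / mean(dists)
}

# centroids of H-maxima regional maxima of a thresholded histogram map,
# with iterative merging of centroids closer than merge_cm
field_centroids_hmax <- function(map, h = 0.8, peak_frac = 0.1,
                                 merge_cm = 25) {
  a <- map$rate
  a[!map$visited] <- NA
  pk <- suppressWarnings(max(a, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0) return(matrix(numeric(0), 0, 3))
  a[a <= peak_frac * pk] <- NA
  labs <- h_maxima(a, h)
  cen <- component_centroids(labs) * map$voxel_cm
  while (nrow(cen) > 1) {
    dd <- as.matrix(dist(cen))
    diag(dd) <- Inf
    w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    if (dd[w[1], w[2]] >= merge_cm) break
    merged <- colMeans(cen[w, , drop = FALSE])
    cen <- rbind(cen[-w, , drop = FALSE], merged)
  }
  cen
}

#' Field distribution across lattice layers
#'
#' Pools field centroids, bins them by lattice layer along each axis, and
#' compares each layer's proportion with a chance distribution from `n_mc`
#' draws of the same number of uniform points (chance is centred on
#' 1/n_layers). Layers outside the 1st-99th percentile band are flagged.
#'
#' @param centroids n x 3 matrix of field centroids, cm.
#' @param environment a lattice `vg_environment`.
#' @param n_mc Monte-Carlo draws.
#' @param seed RNG seed.
#' @return list of per-axis data frames (`layer`, `proportion`, `chance_lo`,
#'   `chance_hi`, `flagged`).
#' @export
layer_distribution_test <- function(centroids, environment =
                                      lattice_environment(), n_mc = 1000,
                                    seed = 1) {
  nl <- environment$n_layers
  size <- environment$size_cm
  nf <- nrow(centroids)
  stopifnot(nf >= 1)
  layer_of <- function(v, len) pmin(pmax(ceiling(v / (len / nl)), 1L), nl)
  chance <- with_seed(seed, {
    lapply(seq_len(n_mc), function(k) {
      u <- matrix(runif(3 * nf), nf, 3) %*% diag(size)
      vapply(1:3, function(ax)
        tabulate(layer_of(u[, ax], size[ax]), nl) / nf, numeric(nl))
    })
  })
  out <- lapply(1:3, function(ax) {
    obs <- tabulate(layer_of(centroids[, ax], size[ax]), nl) / nf
    ch <- vapply(chance, function(m) m[, ax], numeric(nl))
    lo <- apply(ch, 1, quantile, 0.01)
    hi <- apply(ch, 1, quantile, 0.99)
    data.frame(layer = seq_len(nl), proportion = obs,
               chance_mean = rowMeans(ch), chance_lo = lo,
               chance_hi = hi, flagged = obs < lo | obs > hi)
  })
  names(out) <- c("x", "y", "z")
  out
}

#' Field density per cubic metre of sampled space
#'
#' The practical environment volume is the total volume of voxels whose
#' average dwell time exceeds `dwell_thresh`; field density is the field
#' count divided by that volume.
#'
#' @param n_fields number of detected fields.
#' @param dwell_map a histogram [ratemap3d] (its meta `dwell` holds seconds
#'   per voxel), or a plain dwell array in seconds.
#' @param voxel_cm voxel size when `dwell_map` is a plain array.
#' @param dwell_thresh dwell threshold, s.
#' @return list `density_per_m3`, `volume_m3`.
#' @export
fields_per_m3 <- function(n_fields, dwell_map, voxel_cm = NULL,
                          dwell_thresh = 0.1) {
  if (inherits(dwell_map, "vg_ratemap")) {
    dwell <- dwell_map$meta$dwell %||% (dwell_map$occupancy /
                                          dwell_map$sample_rate)
    voxel_cm <- dwell_map$voxel_cm
  } else dwell <- dwell_map
  vol_m3 <- sum(dwell > dwell_thresh, na.rm = TRUE) * (voxel_cm / 100)^3
  if (vol_m3 <= 0) stop("no voxels above the dwell threshold")
  list(density_per_m3 = n_fields / vol_m3, volume_m3 = vol_m3)
}

#' Within-cell consistency of field volumes (CV) against an identity shuffle
#'
#' CV (sd/mean) of one cell's field volumes; the null pools fields across
#' cells, shuffles their cell identities preserving per-cell field counts,
#' and recomputes the per-cell CVs `n` times.
#'
#' @param volumes list of numeric vectors, one per cell (field volumes).
#' @param n shuffles.
#' @param seed RNG seed.
#' @return list `cv` (per cell), `shuffled_cv` (n x cells matrix).
#' @export
field_size_cv <- function(volumes, n = 100, seed = 1) {
  cv1 <- function(v) if (length(v) < 2) NA_real_ else sd(v) / mean(v)
  obs <- vapply(volumes, cv1, numeric(1))
  pool <- unlist(volumes)
  sizes <- lengths(volumes)
  shuf <- with_seed(seed, {
    t(vapply(seq_len(n), function(k) {
      p <- sample(pool)
      splits <- split(p, rep.int(seq_along(sizes), sizes))
      vapply(splits, cv1, numeric(1))
    }, numeric(length(volumes))))
  })
  list(cv = obs, shuffled_cv = shuf)
}
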