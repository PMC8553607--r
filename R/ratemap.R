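#' Volumetric firing-rate maps
#'
#' A `vg_ratemap` ("ratemap3d") wraps a 3D (or 2D, with a singleton third
#' dimension) array of firing rates in Hz with its voxel size, origin,
#' occupancy-sample and spike-count arrays, and a visited-voxel mask. Rates on
#' unvisited voxels are `NA`.
#'
#' @name ratemap3d
NULL

new_ratemap <- function(rate, voxel_cm, origin_cm = c(0, 0, 0),
                        occupancy = NULL, spikes = NULL, alpha = NULL,
                        sample_rate = 25, meta = list()) {
  if (length(dim(rate)) == 2) dim(rate) <- c(dim(rate), 1L)
  visited <- if (!is.null(occupancy)) occupancy > 0 else !is.na(rate)
  structure(list(rate = rate, occupancy = occupancy, spikes = spikes,
                 voxel_cm = voxel_cm, origin_cm = origin_cm,
                 visited = visited, alpha = alpha,
                 sample_rate = sample_rate, meta = meta),
            class = "vg_ratemap")
}

#' @export
print.vg_ratemap <- function(x, ...) {
  d <- dim(x$rate)
  cat(sprintf(
    "<vg_ratemap> %s voxels of %.3g cm, %.0f%% visited, peak %.3g\n",
    paste(d, collapse = "x"), x$voxel_cm,
    100 * mean(x$visited), suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

# trilinear map lookup at positions (n x 3 matrix, cm); coordinates within
# half a voxel of the border clamp to the edge voxel centres
map_value_at <- function(map, pos) {
  d <- dims3(map$rate)
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  cx <- clamp((pos[, 1] - map$origin_cm[1]) / map$voxel_cm + 0.5, d[1])
  cy <- clamp((pos[, 2] - map$origin_cm[2]) / map$voxel_cm + 0.5, d[2])
  cz <- if (d[3] == 1) rep(1, nrow(pos))
        else clamp((pos[, 3] - map$origin_cm[3]) / map$voxel_cm + 0.5, d[3])
  out <- cpp_interp3(map$rate, d, cx, cy, cz)
  # positions more than one voxel outside the map stay NA
  far <- pos[, 1] < map$origin_cm[1] - map$voxel_cm |
    pos[, 1] > map$origin_cm[1] + (d[1] + 1) * map$voxel_cm |
    pos[, 2] < map$origin_cm[2] - map$voxel_cm |
    pos[, 2] > map$origin_cm[2] + (d[2] + 1) * map$voxel_cm
  if (d[3] > 1)
    far <- far | pos[, 3] < map$origin_cm[3] - map$voxel_cm |
      pos[, 3] > map$origin_cm[3] + (d[3] + 1) * map$voxel_cm
  out[far] <- NA
  out
}

map_dims <- function(environment, voxel_cm) {
  size <- environment$size_cm
  d <- pmax(1L, as.integer(round(size / voxel_cm)))
  if (size[3] <= 0) d[3] <- 1L
  d
}

bin_index <- function(pos, voxel_cm, dims, origin = c(0, 0, 0)) {
  ix <- pmin(pmax(ceiling((pos[, 1] - origin[1]) / voxel_cm), 1L), dims[1])
  iy <- pmin(pmax(ceiling((pos[, 2] - origin[2]) / voxel_cm), 1L), dims[2])
  iz <- if (dims[3] == 1L) rep(1L, nrow(pos))
        else pmin(pmax(ceiling((pos[, 3] - origin[3]) / voxel_cm), 1L), dims[3])
  cbind(ix, iy, iz)
}

count_array <- function(idx, dims) {
  lin <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  array(tabulate(lin, nbins = prod(dims)), dim = dims)
}

#' Adaptive-binned firing-rate map
#'
#' For every voxel centre a sphere is expanded in 1-voxel steps until
#' `r > alpha / (n * sqrt(s))`, where `r` is the radius in voxels, `n` the
#' number of occupancy samples and `s` the number of spikes inside; the voxel's
#' rate is then `(s / n) * sample_rate` Hz. The sphere is clipped at the volume
#' boundary. Voxels whose sphere reaches half the volume diagonal without
#' containing a spike get rate 0; inputs are expected to be speed filtered
#' (see [speed_filter()]).
#'
#' @param traj a `vg_trajectory`.
#' @param spikes a `vg_spiketrain`.
#' @param voxel_cm voxel side, cm.
#' @param alpha adaptive-binning constant.
#' @param environment a `vg_environment`; defaults to the trajectory's.
#' @param sample_rate tracking rate used to convert spikes-per-sample to Hz.
#' @return a [ratemap3d].
#' @export
adaptive_ratemap <- function(traj, spikes, voxel_cm = 2.5, alpha = 1600,
                             environment = NULL, sample_rate = 25) {
  environment <- environment %||% traj_env(traj)
  stopifnot(!is.null(environment))
  d <- map_dims(environment, voxel_cm)
  occ <- count_array(bin_index(cbind(traj$x, traj$y, traj$z), voxel_cm, d), d)
  spk <- if (length(spikes))
    count_array(bin_index(position_at(traj, as.numeric(spikes)), voxel_cm, d), d)
  else array(0, dim = d)
  max_r <- as.integer(ceiling(sqrt(sum(d^2)) / 2))
  res <- cpp_adaptive(as.numeric(occ), as.numeric(spk), d, alpha, max_r,
                      sample_rate)
  rate <- array(res$rate, dim = d)
  rate[array(occ, dim = d) == 0 & is.na(rate)] <- NA
  new_ratemap(rate, voxel_cm, occupancy = occ, spikes = spk, alpha = alpha,
              sample_rate = sample_rate,
              meta = list(kind = "adaptive",
                          radius = array(res$radius, dim = d)))
}

#' Histogram firing-rate map with Gaussian smoothing
#'
#' Bins dwell time and spike counts on a regular grid, smooths both with a
#' Gaussian kernel, and divides. Voxels with no raw occupancy are masked
#' (after smoothing). The volumetric stability variant uses 10 cm bins with a
#' 2.5-bin s.d.; the 2D planar variant uses 2.5 cm bins with a 1-bin s.d.
#'
#' @param traj,spikes session data (speed filtered).
#' @param bin_cm bin side, cm.
#' @param smooth_sd Gaussian s.d. in bins; 0 disables smoothing.
#' @param environment a `vg_environment`; defaults to the trajectory's.
#' @param flatten if `TRUE`, ignore z and build a 2D map.
#' @param sample_rate tracking rate, Hz (dwell time per sample).
#' @return a [ratemap3d].
#' @export
histogram_ratemap <- function(traj, spikes, bin_cm = 10, smooth_sd = 2.5,
                              environment = NULL, flatten = FALSE,
                              sample_rate = 25) {
  environment <- environment %||% traj_env(traj)
  stopifnot(!is.null(environment))
  d <- map_dims(environment, bin_cm)
  if (flatten) d[3] <- 1L
  occ <- count_array(bin_index(cbind(traj$x, traj$y, traj$z), bin_cm, d), d)
  if (all(occ == 0)) stop("no dwell anywhere: cannot build a histogram map")
  spk <- if (length(spikes))
    count_array(bin_index(position_at(traj, as.numeric(spikes)), bin_cm, d), d)
  else array(0, dim = d)
  dwell <- occ / sample_rate
  if (smooth_sd > 0) {
    dwell_s <- gauss_smooth(dwell, smooth_sd)
    spk_s <- gauss_smooth(spk * 1.0, smooth_sd)
  } else {
    dwell_s <- dwell
    spk_s <- spk
  }
  rate <- ifelse(dwell_s > 0, spk_s / dwell_s, NA)
  rate[occ == 0] <- NA
  new_ratemap(array(rate, dim = d), bin_cm, occupancy = occ, spikes = spk,
              sample_rate = sample_rate,
              meta = list(kind = "histogram", smooth_sd = smooth_sd,
                          dwell = dwell))
}

#' Project a volumetric rate map onto a coordinate plane
#'
#' Occupancy-weighted collapse along the orthogonal axis: the projected rate is
#' `sum(rate * occupancy) / sum(occupancy)` over visited voxels in each column.
#' Maps without occupancy (synthetic arrangements) use equal weights.
#'
#' @param map a [ratemap3d].
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @return a 2D [ratemap3d] (singleton third dimension).
#' @export
project_ratemap <- function(map, plane = c("XY", "XZ", "YZ")) {
  plane <- match.arg(plane)
  ax <- switch(plane, XY = 3L, XZ = 2L, YZ = 1L)
  keep <- setdiff(1:3, ax)
  w <- if (!is.null(map$occupancy)) map$occupancy * 1.0
       else array(1.0, dim = dim(map$rate))
  w[!map$visited | is.na(map$rate)] <- 0
  r0 <- map$rate
  r0[is.na(r0)] <- 0
  num <- apply(r0 * w, keep, sum)
  den <- apply(w, keep, sum)
  proj <- ifelse(den > 0, num / den, NA)
  occ2 <- if (!is.null(map$occupancy)) apply(map$occupancy, keep, sum)
  new_ratemap(array(proj, dim = c(dim(proj), 1L)), map$voxel_cm,
              origin_cm = c(map$origin_cm[keep], 0), occupancy =
                if (!is.null(occ2)) array(occ2, dim = c(dim(proj), 1L)),
              sample_rate = map$sample_rate,
              meta = list(kind = "projection", plane = plane))
}

#' @export
plot.vg_ratemap <- function(x, plane = "XY", ...) {
  m <- if (dims3(x$rate)[3] > 1) project_ratemap(x, plane)$rate[, , 1]
       else x$rate[, , 1]
  graphics::image(seq_len(nrow(m)) * x$voxel_cm,
                  seq_len(ncol(m)) * x$voxel_cm, m,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "cm", ylab = "cm", useRaster = TRUE, ...)
  invisible(x)
}
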