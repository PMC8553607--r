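#' Generate a close-packed, columnar or random field-centre arrangement
#'
#' Builds the point lattice used to simulate grid-field arrangements. Within a
#' horizontal layer, points are separated by `spacing` along x and
#' `sqrt(3)/2 * spacing` along y, with every second row offset by
#' `spacing / 2` in x, tiling the plane hexagonally. Close-packed stackings
#' separate layers by `sqrt(6)/3 * spacing` along z; HCP alternates two layer
#' placements (ABAB, second layer onwards offset in y by `sqrt(3)/3 * spacing`)
#' while FCC cycles three (ABCABC, third layer onwards offset by
#' `-sqrt(3)/3 * spacing`). Columnar arrangements repeat a single hexagonal
#' layer continuously along z, and random arrangements draw as many uniform
#' points as the matching HCP arrangement contains, inside its bounding box.
#'
#' @param kind one of `"HCP"`, `"FCC"`, `"COL"`, `"RND"`.
#' @param spacing hexagon side length S, mm.
#' @param extent bounding box, mm (length 3); defaults to the 0.97 m lattice
#'   maze cube.
#' @param seed RNG seed (used by `"RND"` only).
#' @return an object of class `vg_arrangement`: a list with `points` (n x 3
#'   matrix, mm), `layer` (stacking-layer index per point), `kind`, `spacing`
#'   and `extent`.
#' @examples
#' arr <- make_arrangement("HCP", spacing = 300)
#' diff(sort(unique(arr$points[, 3])))[1]  # layer z-step = sqrt(6)/3 * 300
#' @export
make_arrangement <- function(kind = c("HCP", "FCC", "COL", "RND"),
                             spacing, extent = rep(970, 3), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, length(extent) == 3, all(extent > 0))
  if (extent[1] < spacing || extent[2] < sqrt(3) / 2 * spacing)
    stop("extent too small to contain one full hexagonal layer")

  if (kind == "RND") {
    hcp <- make_arrangement("HCP", spacing, extent)
    n <- nrow(hcp$points)
    box <- apply(hcp$points, 2, range)
    pts <- with_seed(seed, {
      matrix(runif(3 * n), n, 3) %*% diag(box[2, ] - box[1, ])
    })
    pts <- sweep(pts, 2, box[1, ], `+`)
    out <- list(points = pts, layer = rep(NA_integer_, n), kind = kind,
                spacing = spacing, extent = extent)
    class(out) <- "vg_arrangement"
    return(out)
  }

  S <- spacing
  dy <- sqrt(3) / 2 * S
  dz <- sqrt(6) / 3 * S
  m <- ceiling(max(extent) / min(S, dy)) + 2L

  # rows tiled from the origin: x-spacing S, y-spacing sqrt(3)/2 S, every
  # second row offset by S/2 in x; overfilled then cropped to the extent
  layer_pts <- function(y_offset) {
    ij <- expand.grid(i = -m:m, j = -m:m)
    x <- ij$i * S + (ij$j %% 2) * S / 2
    y <- ij$j * dy + y_offset
    keep <- x >= 0 & x <= extent[1] & y >= 0 & y <= extent[2]
    cbind(x[keep], y[keep])
  }

  if (kind == "COL") {
    xy <- layer_pts(0)
    pts <- cbind(xy, extent[3] / 2)
    lay <- rep(0L, nrow(pts))
  } else {
    zs <- seq(0, extent[3], by = dz)
    pts <- NULL
    lay <- integer(0)
    for (k in seq_along(zs)) {
      off <- if (kind == "HCP") {
        ((k - 1) %% 2) * sqrt(3) / 3 * S
      } else {  # FCC: ABC cycle with offsets 0, +sqrt(3)/3 S, -sqrt(3)/3 S
        c(0, sqrt(3) / 3 * S, -sqrt(3) / 3 * S)[((k - 1) %% 3) + 1]
      }
      xy <- layer_pts(off)
      if (nrow(xy)) {
        pts <- rbind(pts, cbind(xy, zs[k]))
        lay <- c(lay, rep.int(k - 1L, nrow(xy)))
      }
    }
  }
  if (is.null(pts) || nrow(pts) == 0)
    stop("extent too small to contain one full layer")
  out <- list(points = unname(pts), layer = lay, kind = kind,
              spacing = spacing, extent = extent)
  class(out) <- "vg_arrangement"
  out
}

#' @export
print.vg_arrangement <- function(x, ...) {
  cat(sprintf("<vg_arrangement> %s, S = %g mm, %d points, extent %s mm\n",
              x$kind, x$spacing, nrow(x$points),
              paste(round(x$extent), collapse = " x ")))
  invisible(x)
}

#' Rasterise an arrangement into a simulated firing-rate map
#'
#' Every voxel takes the value `g(x) = exp(-0.5 * (x / sigma)^2)` of the
#' Euclidean distance `x` (in voxels) to the nearest field centre, so field
#' centres peak at 1. Columnar arrangements use the in-plane (x, y) distance,
#' producing fields that span the volume vertically. Optionally the finished
#' volume is rotated about an arbitrary axis through its centre (trilinear
#' resampling, zero padding outside the original volume).
#'
#' @param arrangement a `vg_arrangement`.
#' @param voxel_mm voxel side length, mm.
#' @param sigma Gaussian field width in voxels (default 2).
#' @param rotation `NULL`, or `list(axis = <unit 3-vector>, angle = <degrees>)`.
#' @return a [ratemap3d] whose "rate" is the unitless field profile in (0, 1].
#' @export
arrangement_ratemap <- function(arrangement, voxel_mm, sigma = 2,
                                rotation = NULL) {
  stopifnot(inherits(arrangement, "vg_arrangement"),
            nrow(arrangement$points) > 0)
  d <- pmax(2L, as.integer(round(arrangement$extent / voxel_mm)))
  vox <- cbind(pmin(pmax(ceiling(arrangement$points[, 1] / voxel_mm), 1), d[1]),
               pmin(pmax(ceiling(arrangement$points[, 2] / voxel_mm), 1), d[2]),
               pmin(pmax(ceiling(arrangement$points[, 3] / voxel_mm), 1), d[3]))
  if (arrangement$kind == "COL") {
    mask2 <- array(FALSE, dim = c(d[1], d[2], 1L))
    mask2[cbind(vox[, 1], vox[, 2], 1L)] <- TRUE
    dist2 <- sqrt(cpp_sqedt(as.logical(mask2), dims3(mask2)))
    g2 <- exp(-0.5 * (dist2 / sigma)^2)
    vol <- array(rep(g2, d[3]), dim = d)
  } else {
    mask <- array(FALSE, dim = d)
    mask[vox] <- TRUE
    dist <- array(sqrt(cpp_sqedt(as.logical(mask), dims3(mask))), dim = d)
    vol <- exp(-0.5 * (dist / sigma)^2)
  }
  if (!is.null(rotation))
    vol <- rotate_volume(vol, rotation$axis, rotation$angle, pad = 0)
  new_ratemap(rate = vol, voxel_cm = voxel_mm / 10,
              origin_cm = c(0, 0, 0), sample_rate = NA_real_,
              meta = list(kind = arrangement$kind,
                          spacing_mm = arrangement$spacing, sigma = sigma,
                          rotation = rotation))
}
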