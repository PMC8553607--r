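#' Environment descriptors
#'
#' The two apparatus geometries the analyses assume: a square open-field arena
#' (horizontal, treated as 2D) and a cubic climbing-lattice maze with six
#' lattice layers along each axis.
#'
#' @param side_cm side length, cm.
#' @param n_layers number of lattice layers along each axis.
#' @return a `vg_environment` list with `kind`, `size_cm` and `n_layers`.
#' @export
lattice_environment <- function(side_cm = 97, n_layers = 6) {
  structure(list(kind = "lattice", size_cm = rep(side_cm, 3),
                 n_layers = n_layers), class = "vg_environment")
}

#' @rdname lattice_environment
#' @export
arena_environment <- function(side_cm = 120) {
  structure(list(kind = "arena", size_cm = c(side_cm, side_cm, 0),
                 n_layers = 1), class = "vg_environment")
}

#' @rdname lattice_environment
#' @param size_cm box dimensions, cm, for a free-volume environment.
#' @export
volume_environment <- function(size_cm = rep(97, 3)) {
  structure(list(kind = "volume", size_cm = size_cm, n_layers = 1),
            class = "vg_environment")
}

#' Construct a trajectory with derived kinematics
#'
#' Wraps timestamped 3D positions into a `vg_trajectory` data frame. Tracking
#' gaps (NA positions) no longer than `max_gap` seconds are filled by linear
#' interpolation; positions are then smoothed with a Gaussian (`smooth_sd`
#' samples). Derived per-sample quantities: speed (cm/s, finite difference),
#' heading unit vector, azimuth (rad, `atan2(dy, dx)`) and pitch (degrees in
#' [-90, 90]).
#'
#' @param t timestamps, s, strictly increasing.
#' @param x,y,z positions, cm.
#' @param environment a `vg_environment` (attached as an attribute).
#' @param max_gap longest tracking gap filled by interpolation, s.
#' @param smooth_sd positional smoothing s.d. in samples; 0 disables.
#' @return a data frame of class `vg_trajectory` with columns `t, x, y, z,
#'   speed, ux, uy, uz, azimuth, pitch`.
#' @export
trajectory <- function(t, x, y, z = 0, environment = NULL, max_gap = 1,
                       smooth_sd = 2) {
  stopifnot(length(t) > 1, all(diff(t) > 0))
  z <- rep_len(z, length(t))
  fill <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- !is.na(v)
    vi <- approx(t[ok], v[ok], xout = t, rule = 1)$y
    # re-open gaps longer than max_gap
    gap_start <- which(!ok & c(TRUE, ok[-length(ok)]))
    for (g in gap_start) {
      g_end <- g + which(c(ok[g:length(ok)], TRUE))[1] - 2L
      if (g_end >= length(t) || g == 1) { vi[g:min(g_end, length(t))] <- NA; next }
      if (t[g_end + 1] - t[g - 1] > max_gap) vi[g:g_end] <- NA
    }
    vi
  }
  x <- fill(x); y <- fill(y); z <- fill(z)
  keep <- complete.cases(x, y, z)
  t <- t[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (smooth_sd > 0 && length(t) > 5) {
    k <- gauss_kernel(smooth_sd)
    sm <- function(v) {
      r <- (length(k) - 1) / 2
      vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
      as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
    }
    x <- sm(x); y <- sm(y); z <- sm(z)
  }
  n <- length(t)
  dt <- diff(t)
  dx <- diff(x); dy <- diff(y); dz <- diff(z)
  step <- sqrt(dx^2 + dy^2 + dz^2)
  speed <- c(step / dt, 0)
  u <- cbind(dx, dy, dz) / ifelse(step > 0, step, NA)
  u <- rbind(u, u[n - 1, ])
  azimuth <- atan2(c(dy, dy[n - 1]), c(dx, dx[n - 1]))
  pitch <- asin(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
  out <- data.frame(t = t, x = x, y = y, z = z, speed = speed,
                    ux = u[, 1], uy = u[, 2], uz = u[, 3],
                    azimuth = azimuth, pitch = pitch)
  attr(out, "environment") <- environment
  class(out) <- c("vg_trajectory", "data.frame")
  out
}

#' Spike train constructor
#'
#' @param times spike timestamps, s.
#' @param cell_id label for the cell.
#' @return a sorted numeric vector of class `vg_spiketrain`.
#' @export
spiketrain <- function(times, cell_id = "cell") {
  structure(sort(as.numeric(times)), cell_id = cell_id,
            class = "vg_spiketrain")
}

#' @export
print.vg_spiketrain <- function(x, ...) {
  cat(sprintf("<vg_spiketrain> %s: %d spikes over %.1f s\n",
              attr(x, "cell_id"), length(x),
              if (length(x)) diff(range(x)) else 0))
  invisible(x)
}

traj_env <- function(traj) attr(traj, "environment")

# position (interpolated) of the trajectory at arbitrary times
position_at <- function(traj, times) {
  cbind(x = approx(traj$t, traj$x, times, rule = 2)$y,
        y = approx(traj$t, traj$y, times, rule = 2)$y,
        z = approx(traj$t, traj$z, times, rule = 2)$y)
}

#' Remove low-speed epochs from a trajectory and its spike train
#'
#' Samples with running speed below `min_speed` are dropped, as are spikes
#' emitted during the dropped epochs (a spike follows its nearest trajectory
#' sample), so that slow-movement phenomena do not contaminate rate maps.
#'
#' @param traj a `vg_trajectory`.
#' @param spikes a `vg_spiketrain` (or `NULL`).
#' @param min_speed threshold, cm/s.
#' @return `list(traj, spikes)` with the filter applied to both.
#' @export
speed_filter <- function(traj, spikes = NULL, min_speed = 5) {
  keep <- traj$speed >= min_speed
  out_traj <- traj[keep, , drop = FALSE]
  attr(out_traj, "environment") <- traj_env(traj)
  class(out_traj) <- class(traj)
  out_spk <- spikes
  if (!is.null(spikes) && length(spikes)) {
    i <- findInterval(as.numeric(spikes), traj$t, all.inside = TRUE)
    near <- ifelse(abs(traj$t[i] - spikes) <= abs(traj$t[pmin(i + 1, nrow(traj))] - spikes),
                   i, pmin(i + 1, nrow(traj)))
    out_spk <- structure(as.numeric(spikes)[keep[near]],
                         cell_id = attr(spikes, "cell_id"),
                         class = "vg_spiketrain")
  }
  list(traj = out_traj, spikes = out_spk)
}

#' Split a session into vertical- and horizontal-movement epochs
#'
#' Samples moving at a pitch steeper than `pitch_deg` (in absolute value) form
#' the vertical epoch, the rest the horizontal epoch; spikes follow their
#' nearest trajectory sample. The default 30 degrees divides the direction
#' sphere into two halves of equal surface area (an equatorial belt and two
#' caps), so isotropic movement splits evenly.
#'
#' @param traj a `vg_trajectory`.
#' @param spikes a `vg_spiketrain` or `NULL`.
#' @param pitch_deg epoch boundary in degrees.
#' @return `list(vertical = list(traj, spikes), horizontal = list(traj, spikes))`.
#' @export
movement_epoch_split <- function(traj, spikes = NULL, pitch_deg = 30) {
  vert <- abs(traj$pitch) > pitch_deg
  pick <- function(sel) {
    tr <- traj[sel, , drop = FALSE]
    attr(tr, "environment") <- traj_env(traj)
    class(tr) <- class(traj)
    sp <- spikes
    if (!is.null(spikes) && length(spikes)) {
      i <- findInterval(as.numeric(spikes), traj$t, all.inside = TRUE)
      sp <- structure(as.numeric(spikes)[sel[i]],
                      cell_id = attr(spikes, "cell_id"),
                      class = "vg_spiketrain")
    }
    list(traj = tr, spikes = sp)
  }
  list(vertical = pick(vert), horizontal = pick(!vert))
}

#' Read and write sessions as delimited text
#'
#' A session directory holds `trajectory.tsv` (columns `t, x, y, z`) and one
#' `spikes_<cell>.tsv` per cell (column `t`).
#'
#' @param dir session directory.
#' @param traj a `vg_trajectory`.
#' @param spikes a `vg_spiketrain` or list of them.
#' @export
write_session <- function(dir, traj, spikes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(traj[, c("t", "x", "y", "z")],
              file.path(dir, "trajectory.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(spikes, "vg_spiketrain")) spikes <- list(spikes)
  for (sp in spikes) {
    id <- attr(sp, "cell_id") %||% "cell"
    write.table(data.frame(t = as.numeric(sp)),
                file.path(dir, paste0("spikes_", id, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_session
#' @param environment a `vg_environment` to attach to the trajectory.
#' @param ... passed to [trajectory()] (gap filling and smoothing control).
#' @return `read_session`: `list(traj, spikes)` where `spikes` is a named list.
#' @export
read_session <- function(dir, environment = NULL, ...) {
  tr <- read.table(file.path(dir, "trajectory.tsv"), header = TRUE, sep = "\t")
  traj <- trajectory(tr$t, tr$x, tr$y, tr$z, environment = environment, ...)
  spk_files <- list.files(dir, "^spikes_.*\\.tsv$", full.names = TRUE)
  spikes <- lapply(spk_files, function(f) {
    id <- sub("^spikes_(.*)\\.tsv$", "\\1", basename(f))
    spiketrain(read.table(f, header = TRUE, sep = "\t")$t, cell_id = id)
  })
  names(spikes) <- vapply(spikes, attr, "", "cell_id")
  list(traj = traj, spikes = spikes)
}
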