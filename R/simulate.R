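#' Simulate a foraging trajectory
#'
#' Generates a seeded, reproducible trajectory for one of the supported
#' environments. Lattice trajectories are discrete random walks along the
#' maze's climbing bars (axis-aligned segments between lattice nodes) with two
#' behavioural biases observed in volumetric foraging: `horizontal_bias`
#' multiplies the probability of choosing a horizontal bar over a vertical
#' one, and `floor_bias` multiplies the probability of moves ending on the
#' bottom node layer. Arena trajectories are smooth 2D correlated random
#' walks; `"volume"` environments give a dense 3D correlated walk used for
#' space-filling positive controls. Speeds carry Gaussian jitter around
#' `mean_speed`.
#'
#' @param duration session length, s.
#' @param sample_rate tracking rate, Hz.
#' @param environment a `vg_environment`.
#' @param horizontal_bias probability weight (>= 1) favouring horizontal steps.
#' @param floor_bias dwell weight (>= 1) for the bottom layer.
#' @param mean_speed cm/s.
#' @param seed RNG seed.
#' @return a [trajectory()].
#' @export
simulate_trajectory <- function(duration, sample_rate = 25,
                                environment = lattice_environment(),
                                horizontal_bias = 3, floor_bias = 2,
                                mean_speed = 10, seed = NULL) {
  stopifnot(duration > 0, sample_rate > 0, horizontal_bias >= 1,
            floor_bias >= 1)
  n <- round(duration * sample_rate)
  dt <- 1 / sample_rate
  env <- environment
  pos <- with_seed(seed, {
    if (env$kind == "lattice") {
      pitch <- env$size_cm[1] / env$n_layers
      nn <- env$n_layers + 1L
      node <- c(sample.int(nn, 1), sample.int(nn, 1), 1L)  # start on the floor
      out <- matrix(NA_real_, n, 3)
      i <- 1L
      while (i <= n) {
        moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
        cand <- sweep(moves, 2, node, `+`)
        ok <- cand[, 1] >= 1 & cand[, 1] <= nn & cand[, 2] >= 1 &
          cand[, 2] <= nn & cand[, 3] >= 1 & cand[, 3] <= nn
        w <- ifelse(moves[, 3] == 0, horizontal_bias, 1) *
          ifelse(cand[, 3] == 1, floor_bias, 1)
        pick <- sample(which(ok), 1, prob = w[ok])
        nxt <- cand[pick, ]
        sp <- max(2, rnorm(1, mean_speed, 0.2 * mean_speed))
        sp <- min(sp, 2 * mean_speed)
        nstep <- max(1L, round(pitch / (sp * dt)))
        frac <- seq_len(nstep) / nstep
        seg <- cbind((node[1] - 1) + frac * (nxt[1] - node[1]),
                     (node[2] - 1) + frac * (nxt[2] - node[2]),
                     (node[3] - 1) + frac * (nxt[3] - node[3])) * pitch
        take <- min(nstep, n - i + 1L)
        out[i:(i + take - 1L), ] <- seg[seq_len(take), , drop = FALSE]
        i <- i + take
        node <- nxt
      }
      out + matrix(rnorm(3 * n, 0, 0.3), n, 3)  # tracking jitter, cm
    } else {
      flat <- env$kind == "arena"
      size <- env$size_cm
      p <- size / 2
      if (flat) p[3] <- 0
      theta <- runif(1, 0, 2 * pi)
      phi <- 0
      sp <- mean_speed
      out <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        # AR(1) speed: fluctuations persist over ~2 s, as in real foraging
        sp <- mean_speed + 0.98 * (sp - mean_speed) +
          rnorm(1, 0, 0.05 * mean_speed)
        sp <- min(max(sp, 1), 2.5 * mean_speed)
        theta <- theta + rnorm(1, 0, 0.45)
        phi <- if (flat) 0 else 0.8 * phi + rnorm(1, 0, 0.35)
        phi <- max(-1.2, min(1.2, phi))
        step <- sp * dt * c(cos(phi) * cos(theta), cos(phi) * sin(theta),
                            sin(phi))
        p2 <- p + step
        for (ax in 1:3) {
          hi <- if (flat && ax == 3) 0 else size[ax]
          if (p2[ax] < 0) { p2[ax] <- -p2[ax]; theta <- theta + pi }
          if (p2[ax] > hi) { p2[ax] <- 2 * hi - p2[ax]; theta <- theta + pi }
          if (hi == 0) p2[ax] <- 0
        }
        p <- p2
        out[i, ] <- p
      }
      out
    }
  })
  trajectory(t = seq_len(n) * dt, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             environment = env, smooth_sd = 0)
}

#' Draw an inhomogeneous-Poisson spike train from a rate map
#'
#' The expected spike count in each tracking interval is
#' `gain_hz * map value at the current position * dt`; counts are Poisson and
#' spike times are placed uniformly within their interval. Map values are
#' sampled trilinearly; positions outside the map (or on unvisited voxels)
#' contribute rate 0.
#'
#' @param ratemap a [ratemap3d]; its values are multiplied by `gain_hz`, so a
#'   synthetic arrangement map (peak value 1) yields a peak rate of `gain_hz`.
#' @param traj a `vg_trajectory`.
#' @param gain_hz rate scale, Hz.
#' @param seed RNG seed.
#' @return a [spiketrain()].
#' @export
generate_spikes <- function(ratemap, traj, gain_hz = 1, seed = NULL) {
  v <- map_value_at(ratemap, cbind(traj$x, traj$y, traj$z))
  v[is.na(v)] <- 0
  dt <- c(diff(traj$t), 1 / (attr(traj, "sample_rate") %||% 25))
  dt[dt > 1] <- 0  # don't spike across tracking gaps
  lam <- gain_hz * v * dt
  times <- with_seed(seed, {
    counts <- rpois(length(lam), lam)
    idx <- rep.int(seq_along(counts), counts)
    if (!length(idx)) numeric(0)
    else traj$t[idx] + dt[idx] * runif(length(idx))
  })
  spiketrain(times, cell_id = "sim")
}

#' Simulate a complete recording session for one synthetic cell
#'
#' Convenience wrapper: builds the field arrangement, rasterises it to the
#' ground-truth rate map, simulates a lattice (or volume) trajectory, and draws
#' spikes. All randomness is derived deterministically from `seed`.
#'
#' @param kind arrangement kind (`"HCP"`, `"FCC"`, `"COL"`, `"RND"`).
#' @param spacing hexagon side length S, mm; by default drawn uniformly from
#'   200--600 mm.
#' @param duration session length, s.
#' @param voxel_mm ground-truth map voxel, mm.
#' @param sigma field width, voxels.
#' @param rotation `NULL`, `"random30"` for a 30-degree rotation about a random
#'   axis, or `list(axis=, angle=)`.
#' @param gain_hz peak firing rate, Hz.
#' @param environment environment for the trajectory (default: dense volume
#'   walk over the lattice-maze cube).
#' @param seed master seed.
#' @param ... further arguments to [simulate_trajectory()].
#' @return `list(arrangement, map, traj, spikes)`.
#' @export
synthetic_session <- function(kind, spacing = NULL, duration = 1200,
                              voxel_mm = 970 / 21, sigma = 2,
                              rotation = NULL, gain_hz = 10,
                              environment = volume_environment(),
                              seed = 1, ...) {
  if (is.null(spacing))
    spacing <- with_seed(derive_seed(seed, 1), runif(1, 200, 600))
  if (identical(rotation, "random30")) {
    ax <- with_seed(derive_seed(seed, 2), {
      v <- rnorm(3); v / sqrt(sum(v^2))
    })
    rotation <- list(axis = ax, angle = 30)
  }
  arr <- make_arrangement(kind, spacing, extent = environment$size_cm * 10,
                          seed = derive_seed(seed, 3))
  map <- arrangement_ratemap(arr, voxel_mm = voxel_mm, sigma = sigma,
                             rotation = rotation)
  traj <- simulate_trajectory(duration, environment = environment,
                              seed = derive_seed(seed, 4), ...)
  spikes <- generate_spikes(map, traj, gain_hz = gain_hz,
                            seed = derive_seed(seed, 5))
  list(arrangement = arr, map = map, traj = traj, spikes = spikes)
}
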