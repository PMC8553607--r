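# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Un-rotated FCC arrangement map at the 41^3-autocorrelation resolution
fcc_map <- function() fixture("fcc_map", function() {
  arrangement_ratemap(make_arrangement("FCC", 400), voxel_mm = 970 / 21)
})

fcc_ac <- function() fixture("fcc_ac", function() autocorrelation(fcc_map()))

# Dense-coverage volumetric session from the same arrangement
fcc_session <- function() fixture("fcc_session", function() {
  synthetic_session("FCC", spacing = 400, duration = 1200,
                    voxel_mm = 970 / 21, gain_hz = 25, seed = 7)
})

# 2D hexagonal autocorrelogram from one columnar layer
hex_ac2d <- function() fixture("hex_ac2d", function() {
  m <- arrangement_ratemap(make_arrangement("COL", 300), voxel_mm = 20)
  m$rate <- m$rate[, , 1, drop = FALSE]
  m$visited <- m$visited[, , 1, drop = FALSE]
  autocorrelation(m)
})

# 2D square-lattice autocorrelogram
square_ac2d <- function() fixture("square_ac2d", function() {
  d <- c(40, 40)
  co <- arrayInd(seq_len(prod(d)), d)
  ctr <- expand.grid(x = seq(4, 40, 8), y = seq(4, 40, 8))
  dist2 <- rep(Inf, prod(d))
  for (i in seq_len(nrow(ctr)))
    dist2 <- pmin(dist2, (co[, 1] - ctr$x[i])^2 + (co[, 2] - ctr$y[i])^2)
  sq <- array(exp(-0.5 * dist2 / 4), dim = c(d, 1))
  autocorrelation(sq)
})

# Arena session of a spatially uniform Poisson cell
poisson_arena <- function(rate_hz = 5, duration = 300, seed = 1) {
  traj <- simulate_trajectory(duration, environment = arena_environment(),
                              seed = seed)
  n <- nrow(traj)
  spikes <- with_seed(seed + 1000, {
    counts <- rpois(n, rate_hz * 0.04)
    spiketrain(rep(traj$t, counts) - runif(sum(counts), 0, 0.04))
  })
  list(traj = traj, spikes = spikes)
}

with_seed <- volgrid:::with_seed
derive_seed <- volgrid:::derive_seed
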