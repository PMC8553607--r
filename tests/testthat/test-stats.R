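make_map <- function(rates, occ) {
  d <- c(length(rates), 1L, 1L)
  volgrid:::new_ratemap(array(rates, dim = d), 1,
                        occupancy = array(occ, dim = d))
}

test_that("spatial information matches hand-computed values", {
  two <- spatial_information(make_map(c(2, 0), c(10, 10)))
  expect_equal(two$spatial_info_rate, 1)
  expect_equal(two$spatial_info_spike, 1)
  expect_equal(two$sparsity, 0.5)

  unif <- spatial_information(make_map(rep(3, 8), rep(5, 8)))
  expect_equal(unif$spatial_info_rate, 0)
  expect_equal(unif$sparsity, 1)

  zero <- spatial_information(make_map(rep(0, 4), rep(5, 4)))
  expect_equal(zero$spatial_info_rate, 0)
})

test_that("rate and per-spike information obey the exact identity", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    info <- spatial_information(make_map(rexp(n), sample(1:20, n, TRUE)))
    expect_equal(info$spatial_info_rate,
                 info$mean_rate_hz * info$spatial_info_spike,
                 tolerance = 1e-12)
    expect_gte(info$spatial_info_spike, 0)
    expect_true(info$sparsity > 0 && info$sparsity <= 1)
  }
})

test_that("sparsity decreases under mean-preserving concentration", {
  sp <- vapply(c(0, 0.5, 0.9), function(f) {
    spatial_information(make_map(c(1 + f, 1 - f), c(10, 10)))$sparsity
  }, numeric(1))
  expect_true(all(diff(sp) < 0))
})

test_that("shuffle standardisation is affine invariant", {
  ses <- poisson_arena(rate_hz = 8, duration = 120, seed = 6)
  base <- function(traj, sp) length(sp) + sum(head(as.numeric(sp), 3))
  z1 <- spike_shift_shuffle(ses$traj, ses$spikes, base, n = 30, seed = 3)$z
  z2 <- spike_shift_shuffle(ses$traj, ses$spikes,
                            function(a, b) 100 * base(a, b) - 7,
                            n = 30, seed = 3)$z
  expect_equal(z1, z2, tolerance = 1e-9)
  short <- ses$traj[ses$traj$t < 30, ]
  class(short) <- class(ses$traj)
  expect_error(spike_shift_shuffle(short, ses$spikes, base), "short")
})

test_that("split-half stability separates stable from unstable cells", {
  # volumetric variant: multi-field cell in a densely sampled cube
  env <- volume_environment(c(60, 60, 60))
  traj <- simulate_trajectory(1200, environment = env, seed = 77,
                              mean_speed = 20)
  d <- c(24L, 24L, 24L)
  co <- arrayInd(seq_len(prod(d)), d)
  pts <- rbind(c(6, 6, 6), c(6, 18, 12), c(18, 6, 18), c(18, 18, 6),
               c(12, 12, 12))
  dist2 <- rep(Inf, prod(d))
  for (i in seq_len(nrow(pts)))
    dist2 <- pmin(dist2, rowSums(sweep(co, 2, pts[i, ])^2))
  map <- volgrid:::new_ratemap(array(10 * exp(-0.5 * dist2 / 9), dim = d),
                               2.5)
  spikes <- generate_spikes(map, traj, gain_hz = 1, seed = 78)
  st <- split_half_stability(traj, spikes, "volumetric", environment = env)
  expect_gt(st$r, 0.5)
  rnd <- spiketrain(sort(runif(length(spikes), 0, 1200)))
  st0 <- split_half_stability(traj, rnd, "volumetric", environment = env)
  expect_lt(st0$r, st$r)

  # planar variant on an arena session; identical halves give r = 1
  aenv <- arena_environment(side_cm = 100)
  layer <- make_arrangement("COL", 550, extent = c(1000, 1000, 200))
  map2d <- arrangement_ratemap(layer, voxel_mm = 50)
  map2d$rate <- map2d$rate[, , 1, drop = FALSE] * 10
  map2d$visited <- !is.na(map2d$rate)
  atraj <- simulate_trajectory(300, environment = aenv, seed = 41)
  aspk <- generate_spikes(map2d, atraj, gain_hz = 1, seed = 42)
  stp <- split_half_stability(atraj, aspk, "planar", environment = aenv)
  expect_gt(stp$r, 0.5)

  n <- nrow(atraj)
  half <- atraj[seq_len(n / 2), ]
  t2 <- c(half$t, half$t + max(half$t))
  dup <- trajectory(t2, rep(half$x, 2), rep(half$y, 2), 0,
                    environment = aenv, smooth_sd = 0)
  sp_half <- as.numeric(aspk)[as.numeric(aspk) <= max(half$t)]
  dup_sp <- spiketrain(c(sp_half, sp_half + max(half$t)))
  st1 <- split_half_stability(dup, dup_sp, "planar", environment = aenv)
  expect_equal(st1$r, 1, tolerance = 0.02)
})

test_that("mismatched-cell stability null centres near zero", {
  env <- arena_environment(side_cm = 100)
  maps <- lapply(1:4, function(s) {
    traj <- simulate_trajectory(400, environment = env, seed = 50 + s,
                                mean_speed = 15)
    sp <- spiketrain(sort(runif(2000, 0, 400)))
    tmid <- 200
    first <- histogram_ratemap(
      {h <- traj[traj$t <= tmid, ]; class(h) <- class(traj)
       attr(h, "environment") <- env; h},
      spiketrain(as.numeric(sp)[as.numeric(sp) <= tmid]),
      bin_cm = 10, smooth_sd = 2.5, environment = env)
    second <- histogram_ratemap(
      {h <- traj[traj$t > tmid, ]; class(h) <- class(traj)
       attr(h, "environment") <- env; h},
      spiketrain(as.numeric(sp)[as.numeric(sp) > tmid]),
      bin_cm = 10, smooth_sd = 2.5, environment = env)
    list(first = first, second = second)
  })
  null <- stability_null(maps, n_pairs = 200, seed = 7)
  expect_lt(abs(mean(null, na.rm = TRUE)), 0.25)
})

test_that("directional tuning recovers a von Mises preference", {
  env <- arena_environment()
  traj <- simulate_trajectory(600, environment = env, seed = 61)
  az <- traj$azimuth
  lam <- 3 * exp(2 * cos(az - pi / 2))  # kappa = 2, mu = 90 deg
  set.seed(62)
  cnt <- rpois(nrow(traj), lam * 0.04)
  spikes <- spiketrain(rep(traj$t, cnt))
  dt <- directional_tuning(traj, spikes)
  expect_equal(length(dt$rate_hz), 60)
  err <- abs(dt$preferred_deg - 90)
  expect_lte(min(err, 360 - err), 12)
  expect_gt(dt$rayleigh, 0.3)

  unif <- spiketrain(sort(runif(10000, 0, 600)))
  d0 <- directional_tuning(traj, unif)
  expect_lt(d0$rayleigh, 0.1)
})

test_that("directional population stability detects allocentric stability", {
  set.seed(71)
  curves <- lapply(1:6, function(i) pmax(0, circ_smooth(rexp(60), 2)))
  same <- directional_population_stability(curves, curves, n = 200, seed = 2)
  expect_equal(same$r, 1)
  expect_true(same$significant)

  indep <- lapply(1:6, function(i) pmax(0, circ_smooth(rexp(60), 2)))
  r0 <- directional_population_stability(curves, indep, n = 200, seed = 3)
  expect_lt(abs(r0$r), 0.4)

  # a shared shift of all lattice curves breaks the pooled correlation
  shifted <- lapply(curves, function(v) c(v[16:60], v[1:15]))
  rs <- directional_population_stability(curves, shifted, n = 200, seed = 4)
  expect_lt(rs$r, same$r - 0.3)
})
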