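test_that("simulated trajectories are confined, continuous and reproducible", {
  for (env in list(lattice_environment(), arena_environment(),
                   volume_environment())) {
    tr <- simulate_trajectory(60, environment = env, seed = 11)
    expect_equal(nrow(tr), 60 * 25)
    expect_true(all(tr$x >= -1 & tr$x <= env$size_cm[1] + 1))
    expect_true(all(tr$z >= -1 & tr$z <= max(env$size_cm[3], 0) + 1))
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    expect_lt(max(step), 10 * 3 / 25 + 1.5)  # no teleports
  }
  a <- simulate_trajectory(30, seed = 5)
  b <- simulate_trajectory(30, seed = 5)
  expect_identical(a$x, b$x)
})

test_that("the lattice walk expresses floor and horizontal biases", {
  tr <- simulate_trajectory(600, environment = lattice_environment(),
                            horizontal_bias = 3, floor_bias = 2, seed = 2)
  expect_gt(mean(tr$z < 97 / 6), 1 / 6)           # floor over-represented
  expect_gt(mean(abs(tr$pitch) < 30, na.rm = TRUE), 0.5)  # mostly horizontal
})

test_that("speed filtering drops slow epochs and their spikes", {
  n <- 1000
  t <- seq_len(n) / 25
  # alternating slow/fast epochs of equal length
  fast <- rep_len(rep(c(FALSE, TRUE), each = 100), n)
  dx <- ifelse(fast, 0.6, 0.05)
  tr <- trajectory(t, cumsum(dx), rep(0, n), 0,
                   environment = arena_environment(), smooth_sd = 0)
  spk <- spiketrain(t)
  out <- speed_filter(tr, spk, min_speed = 5)
  expect_equal(nrow(out$traj) / n, 0.5, tolerance = 0.05)
  expect_equal(length(out$spikes) / n, 0.5, tolerance = 0.05)
  expect_true(all(out$traj$speed >= 5))

  still <- trajectory(t, rep(1, n), rep(1, n), 0, smooth_sd = 0)
  expect_equal(nrow(speed_filter(still, spk)$traj), 0)
})

test_that("movement epochs split at the equal-area 30-degree pitch", {
  n <- 2000
  t <- seq_len(n) / 25
  flat <- trajectory(t, cumsum(rep(0.4, n)), rep(0, n), 0, smooth_sd = 0)
  sp <- movement_epoch_split(flat, NULL)
  expect_equal(nrow(sp$vertical$traj), 0)
  expect_equal(nrow(sp$horizontal$traj), n)

  # isotropic random headings: the 30-degree belt covers half the sphere
  set.seed(8)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- apply(u * 0.5, 2, cumsum)
  iso <- trajectory(t, pos[, 1], pos[, 2], pos[, 3], smooth_sd = 0)
  spl <- movement_epoch_split(iso, NULL)
  frac <- nrow(spl$vertical$traj) / n
  expect_equal(frac, 0.5, tolerance = 0.05)
  expect_equal(nrow(spl$vertical$traj) + nrow(spl$horizontal$traj), n)
})

test_that("session round-trips through delimited text", {
  tr <- simulate_trajectory(20, environment = arena_environment(), seed = 3)
  sp <- spiketrain(sort(runif(40, 0, 20)), cell_id = "c1")
  dir <- tempfile("session")
  write_session(dir, tr, sp)
  back <- read_session(dir, environment = arena_environment(), smooth_sd = 0)
  expect_equal(back$traj$x, tr$x, tolerance = 1e-6)
  expect_equal(as.numeric(back$spikes$c1), as.numeric(sp), tolerance = 1e-6)
})

test_that("spike generation is inhomogeneous Poisson against the map", {
  env <- volume_environment()
  tr <- simulate_trajectory(600, environment = env, seed = 21)
  flat <- volgrid:::new_ratemap(array(1, dim = c(10, 10, 10)), 9.7,
                                sample_rate = 25)
  sp <- generate_spikes(flat, tr, gain_hz = 5, seed = 9)
  expect_equal(length(sp), 5 * 600, tolerance = 0.1)
  zero <- volgrid:::new_ratemap(array(0, dim = c(10, 10, 10)), 9.7)
  expect_equal(length(generate_spikes(zero, tr, gain_hz = 5, seed = 9)), 0)
  s1 <- generate_spikes(flat, tr, gain_hz = 5, seed = 4)
  s2 <- generate_spikes(flat, tr, gain_hz = 5, seed = 4)
  expect_identical(as.numeric(s1), as.numeric(s2))
})
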