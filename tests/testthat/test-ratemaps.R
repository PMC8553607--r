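test_that("the adaptive-binning criterion matches its closed form", {
  # all occupancy and spikes in the centre voxel: n = 100 samples, s = 16
  # spikes, so the expansion stops at the first radius r with
  # r > 1600 / (100 * sqrt(16)) = 4, i.e. r = 5, and the rate is
  # (16 / 100) * 25 = 4 Hz
  d <- c(15L, 15L, 15L)
  occ <- spk <- array(0, dim = d)
  occ[8, 8, 8] <- 100
  spk[8, 8, 8] <- 16
  res <- volgrid:::cpp_adaptive(as.numeric(occ), as.numeric(spk), d,
                                1600, 13L, 25)
  rate <- array(res$rate, dim = d)
  radius <- array(res$radius, dim = d)
  expect_equal(rate[8, 8, 8], 4)
  expect_equal(radius[8, 8, 8], 5)
})

test_that("adaptive maps recover a homogeneous Poisson rate", {
  ses <- poisson_arena(rate_hz = 5, duration = 600, seed = 2)
  sf <- speed_filter(ses$traj, ses$spikes)
  m <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 5,
                        environment = arena_environment())
  vals <- m$rate[m$visited & !is.na(m$rate)]
  expect_equal(median(vals), 5, tolerance = 0.15)
})

test_that("a session with no spikes maps to zero, not NA, where visited", {
  ses <- poisson_arena(rate_hz = 5, duration = 60, seed = 3)
  sf <- speed_filter(ses$traj, spiketrain(numeric(0)))
  m <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 5,
                        environment = arena_environment())
  expect_true(all(m$rate[m$visited] == 0))
})

test_that("histogram maps conserve spike mass", {
  ses <- poisson_arena(rate_hz = 4, duration = 300, seed = 4)
  sf <- speed_filter(ses$traj, ses$spikes)
  raw <- histogram_ratemap(sf$traj, sf$spikes, bin_cm = 10, smooth_sd = 0,
                           environment = arena_environment())
  dwell <- raw$meta$dwell
  got <- sum(raw$rate * dwell, na.rm = TRUE)
  expect_equal(got, length(sf$spikes), tolerance = 1e-6)

  sm <- histogram_ratemap(sf$traj, sf$spikes, bin_cm = 10, smooth_sd = 1,
                          environment = arena_environment())
  mass_sm <- sum(sm$rate * sm$meta$dwell, na.rm = TRUE)
  expect_equal(mass_sm, length(sf$spikes), tolerance = 0.05)
})

test_that("single-spike histogram map puts 1 Hz in the right voxel", {
  t <- seq_len(100) / 25
  tr <- trajectory(t, rep(30, 100), rep(30, 100), 0,
                   environment = arena_environment(), smooth_sd = 0)
  m <- histogram_ratemap(tr, spiketrain(2), bin_cm = 10, smooth_sd = 0)
  expect_equal(m$rate[3, 3, 1], 1 / 4, tolerance = 1e-9)  # 1 spike / 4 s
  expect_equal(sum(m$rate > 0, na.rm = TRUE), 1)
})

test_that("projections collapse by occupancy weighting", {
  r <- array(NA_real_, dim = c(2, 2, 2))
  occ <- array(0, dim = c(2, 2, 2))
  r[1, 1, 1] <- 2; r[1, 1, 2] <- 4
  occ[1, 1, 1] <- 10; occ[1, 1, 2] <- 10
  m <- volgrid:::new_ratemap(r, 1, occupancy = occ)
  p <- project_ratemap(m, "XY")
  expect_equal(p$rate[1, 1, 1], 3)
  # unequal occupancy weights
  occ[1, 1, 2] <- 30
  m2 <- volgrid:::new_ratemap(r, 1, occupancy = occ)
  expect_equal(project_ratemap(m2, "XY")$rate[1, 1, 1],
               (2 * 10 + 4 * 30) / 40)
  # constant maps project to the constant
  rc <- array(3, dim = c(4, 4, 4))
  mc <- volgrid:::new_ratemap(rc, 1)
  expect_true(all(abs(project_ratemap(mc, "XZ")$rate - 3) < 1e-12))
})

test_that("adaptive and histogram maps of dense data agree", {
  ses <- fcc_session()
  sf <- speed_filter(ses$traj, ses$spikes)
  env <- volume_environment()
  am <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 97 / 21,
                         environment = env)
  hm <- histogram_ratemap(sf$traj, sf$spikes, bin_cm = 97 / 21,
                          smooth_sd = 1.5, environment = env)
  ok <- !is.na(am$rate) & !is.na(hm$rate)
  expect_gt(cor(am$rate[ok], hm$rate[ok]), 0.7)
})

test_that("adaptive maps reproduce the generating arrangement", {
  ses <- fcc_session()
  sf <- speed_filter(ses$traj, ses$spikes)
  am <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 97 / 21,
                         environment = volume_environment())
  ok <- am$visited & !is.na(am$rate) & !is.na(ses$map$rate)
  expect_gt(cor(am$rate[ok], ses$map$rate[ok]), 0.8)
})
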