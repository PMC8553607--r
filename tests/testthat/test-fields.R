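test_that("field detection recovers the generator's field count", {
  for (kind in c("FCC", "HCP")) {
    arr <- make_arrangement(kind, 420, seed = 1)
    m <- arrangement_ratemap(arr, voxel_mm = 970 / 21, sigma = 1.6)
    fl <- detect_fields(m, NULL, min_voxels = 10, min_peak_hz = 0.5)
    expect_lte(abs(nrow(fl) - nrow(arr$points)), 1)
  }
  empty <- volgrid:::new_ratemap(array(0, dim = c(8, 8, 8)), 2.5)
  expect_equal(nrow(detect_fields(empty)), 0)
})

test_that("sub-peak and rarely-visited fields are excluded", {
  d <- c(24L, 24L, 1L)
  a <- array(0, dim = d)
  co <- arrayInd(seq_len(prod(d)), d)
  d1 <- sqrt((co[, 1] - 6)^2 + (co[, 2] - 6)^2)
  d2 <- sqrt((co[, 1] - 18)^2 + (co[, 2] - 18)^2)
  a[] <- 5 * exp(-0.5 * (d1 / 3)^2) + 0.5 * exp(-0.5 * (d2 / 3)^2)
  m <- volgrid:::new_ratemap(array(a, dim = d), 2.5)
  fl <- detect_fields(m, NULL, min_voxels = 4, min_peak_hz = 1)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$peak_hz[1], 5, tolerance = 0.05)
})

test_that("principal axes match analytic ellipsoid moments", {
  co <- arrayInd(seq_len(41 * 21 * 21), c(41L, 21L, 21L))
  inside <- ((co[, 1] - 21) / 20)^2 + ((co[, 2] - 11) / 10)^2 +
    ((co[, 3] - 11) / 10)^2 <= 1
  ax <- field_axes_voxels(co[inside, ])
  expect_equal(ax$lengths[1] / ax$lengths[2], 2, tolerance = 0.05)
  expect_equal(ax$lengths[2] / ax$lengths[3], 1, tolerance = 0.05)
  expect_equal(crossprod(ax$vectors), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(ax$vectors[1, 1]), 1, tolerance = 1e-6)

  sphere <- co[(co[, 1] - 21)^2 + (co[, 2] - 11)^2 + (co[, 3] - 11)^2 <= 81, ]
  axs <- field_axes_voxels(sphere)
  expect_equal(elongation_index(axs$lengths), 1, tolerance = 0.03)
})

test_that("elongation and equivalent-diameter formulas are exact", {
  expect_equal(elongation_index(c(4, 2, 2)), 2)
  expect_equal(elongation_index(c(3, 3), dims = 2), 1)
  expect_equal(equivalent_diameter(pi / 6), 1)
})

test_that("convex volume approximates a known box", {
  co <- arrayInd(seq_len(6 * 6 * 6), c(6L, 6L, 6L))
  v <- convex_volume(co, voxel_cm = 1, n_samples = 4000, seed = 2)
  expect_equal(v, 216, tolerance = 0.1)  # the filled box is its own hull
})

test_that("field shuffle conserves values, peak and unvisited bins exactly", {
  ses <- fcc_session()
  sf <- speed_filter(ses$traj, ses$spikes)
  m <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 97 / 15,
                        environment = volume_environment())
  sh <- field_shuffle(m, seed = 3)
  src <- m$rate
  src[!m$visited] <- NA   # the map's values live on visited bins only
  expect_identical(is.na(sh$rate), is.na(src))
  expect_identical(sort(sh$rate[!is.na(sh$rate)]), sort(src[!is.na(src)]))
  expect_equal(max(sh$rate, na.rm = TRUE), max(src, na.rm = TRUE))
  # and it actually moves mass around
  expect_gt(mean(sh$rate != src, na.rm = TRUE), 0.2)
})

test_that("orientation test matches the spherical-cap chance level", {
  set.seed(12)
  u <- matrix(rnorm(3 * 400), 400, 3)
  u <- u / sqrt(rowSums(u^2))
  res <- orientation_axis_test(u, n_mc = 400, seed = 5)
  expect_equal(res$proportion, rep(1 - cos(30 * pi / 180), 3),
               tolerance = 0.35)
  expect_false(any(res$flagged))

  allz <- matrix(rep(c(0, 0, 1), each = 50), 50, 3)
  rz <- orientation_axis_test(allz, n_mc = 200, seed = 6)
  expect_true(rz$flagged[3])
  expect_equal(rz$count[3], 50)
  expect_equal(rz$count[1], 0)
})

test_that("spherical kernel density peaks at the data", {
  v <- matrix(c(0, 0, 1), 1, 3)
  dn <- vmf_density(v, sigma = 10)
  expect_equal(unname(dn$dirs[which.max(dn$density), ]), c(0, 0, 1),
               tolerance = 0.05)
  anti <- rbind(c(1, 0, 0), c(-1, 0, 0))
  da <- vmf_density(anti, sigma = 10)
  top2 <- order(da$density, decreasing = TRUE)[1:2]
  expect_equal(abs(da$dirs[top2, 1]), c(1, 1), tolerance = 0.05)
})

test_that("interfield distances of a close packing have near-zero CV", {
  arr <- make_arrangement("HCP", 400)
  expect_lt(interfield_distance_cv(arr$points / 10), 0.05)
  set.seed(3)
  rnd <- matrix(runif(3 * 40, 0, 97), 40, 3)
  expect_gt(interfield_distance_cv(rnd),
            interfield_distance_cv(arr$points / 10))
  expect_true(is.na(interfield_distance_cv(matrix(1, 1, 3))))
})

test_that("field centroids are recovered and merged from histogram maps", {
  arr <- make_arrangement("HCP", 400)
  m <- arrangement_ratemap(arr, voxel_mm = 970 / 31)
  m$rate <- m$rate * 8
  cen <- volgrid:::field_centroids_hmax(m, h = 0.8, merge_cm = 25 / 10)
  expect_equal(nrow(cen), nrow(arr$points), tolerance = 0.1)
})

test_that("layer distribution flags gross violations only", {
  env <- lattice_environment()
  set.seed(9)
  cen <- matrix(runif(3 * 60, 0, 97), 60, 3)
  res <- layer_distribution_test(cen, env, n_mc = 300, seed = 2)
  expect_equal(mean(vapply(res, function(df) mean(df$chance_lo), 1)) <
                 1 / 6, TRUE)
  expect_lt(sum(vapply(res, function(df) sum(df$flagged), 1)), 3)

  stacked <- cbind(runif(60, 0, 97), runif(60, 0, 97), runif(60, 0, 10))
  rs <- layer_distribution_test(stacked, env, n_mc = 300, seed = 3)
  expect_true(rs$z$flagged[1])
  expect_equal(rs$z$proportion[1], 1)
})

test_that("field density uses only well-sampled volume", {
  dwell <- array(1, dim = c(10, 10, 10))  # 1 s everywhere, 10 cm voxels
  out <- fields_per_m3(3, dwell, voxel_cm = 10)
  expect_equal(out$volume_m3, 1)
  expect_equal(out$density_per_m3, 3)
  dwell[1:5, , ] <- 0.05
  out2 <- fields_per_m3(3, dwell, voxel_cm = 10, dwell_thresh = 0.1)
  expect_lt(out2$volume_m3, 1)
  out3 <- fields_per_m3(3, dwell, voxel_cm = 10, dwell_thresh = 0.2)
  expect_lte(out3$volume_m3, out2$volume_m3)
})

test_that("field-volume CV and its identity shuffle behave", {
  expect_equal(field_size_cv(list(a = c(1, 2, 3)))$cv[["a"]], 0.5)
  expect_equal(field_size_cv(list(a = c(2, 2, 2)))$cv[["a"]], 0)
  vols <- list(a = c(10, 11, 12), b = c(50, 55, 60), c = c(100, 110))
  out <- field_size_cv(vols, n = 50, seed = 4)
  expect_equal(dim(out$shuffled_cv), c(50, 3))
  # pooled shuffles mix scales, so shuffled CVs exceed the within-cell CVs
  expect_gt(mean(out$shuffled_cv, na.rm = TRUE), mean(out$cv))
})

test_that("spherical fields rarely flag as elongated; stretched ones do", {
  env <- volume_environment(c(60, 60, 60))
  traj <- simulate_trajectory(1800, environment = env, seed = 13,
                              mean_speed = 14)
  d <- c(24L, 24L, 24L)
  co <- arrayInd(seq_len(prod(d)), d)
  mk <- function(sx, s0 = 3) {
    dist2 <- ((co[, 1] - 12) / sx)^2 + ((co[, 2] - 12) / s0)^2 +
      ((co[, 3] - 12) / s0)^2
    volgrid:::new_ratemap(array(8 * exp(-0.5 * dist2), dim = d), 2.5)
  }
  run <- function(map, seed) {
    spikes <- generate_spikes(map, traj, gain_hz = 3, seed = seed)
    sf <- speed_filter(traj, spikes)
    m <- adaptive_ratemap(sf$traj, sf$spikes, voxel_cm = 2.5,
                          environment = env)
    fl <- detect_fields(m, traj, min_voxels = 20)
    expect_gte(nrow(fl), 1)
    elongation_shuffle(fl, which.max(fl$n_voxels), traj, spikes, m,
                       n = 30, seed = seed)
  }
  zs <- vapply(1:4, function(s) run(mk(3), 100 + s)$z, numeric(1))
  expect_lte(sum(zs > 1.96), 1)          # type-I control on spheres
  stretched <- run(mk(9), 55)            # 3:1 elongated field
  expect_gt(stretched$z, 1.96)
  expect_true(stretched$nonspherical)
})
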