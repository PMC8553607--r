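test_that("plane sampling covers the advertised grid", {
  sph <- sample_planes(fcc_ac(), 33, 33)
  expect_equal(length(sph$pitch) * length(sph$azimuth), 33 * 33)
  expect_equal(range(sph$pitch), c(0, 90))
  expect_lt(max(sph$azimuth), 360)
  # the horizontal row is constant across azimuths
  expect_equal(sd(sph$hgs_map[1, ]), 0)
})

test_that("small volumes are rejected for slicing", {
  tiny <- list(r = array(runif(1000), dim = c(10, 10, 10)),
               m = array(100L, dim = c(10, 10, 10)),
               lag_voxel_cm = 1, center = c(5L, 5L, 5L))
  class(tiny) <- "vg_autocorr"
  expect_error(sample_planes(tiny), "too small")
})

test_that("columnar maps score best at horizontal planes", {
  m <- arrangement_ratemap(make_arrangement("COL", 350), voxel_mm = 970 / 21)
  sph <- sample_planes(autocorrelation(m), 33, 33)
  bp <- best_plane(sph)
  expect_lte(bp[1], 12)
  band <- rowMeans(sph$hgs_map, na.rm = TRUE)
  expect_gt(mean(band[sph$pitch <= 30], na.rm = TRUE),
            mean(band[sph$pitch >= 60], na.rm = TRUE))
})

test_that("sphere interpolation is a faithful nearest-neighbour regrid", {
  sph <- sample_planes(fcc_ac(), 17, 17)
  si <- interpolate_sphere(sph, 65)
  # native grid points retain their values (65 = 4*16+1 nests 17 pitches)
  expect_equal(si$hgs_map[seq(1, 65, 4), 1], sph$hgs_map[, 1])
  const <- sph
  const$hgs_map[] <- 0.5
  const$sgs_map[] <- -0.1
  ci <- interpolate_sphere(const, 33)
  expect_true(all(ci$hgs_map == 0.5))
  expect_true(all(ci$sgs_map == -0.1))
})

test_that("best-plane correction recovers a known tilt", {
  m <- arrangement_ratemap(make_arrangement("COL", 350), voxel_mm = 970 / 21,
                           rotation = list(axis = c(0, 1, 0), angle = 30))
  sph <- sample_planes(autocorrelation(m), 33, 33)
  bp <- best_plane(sph)
  expect_equal(unname(bp[1]), 30, tolerance = 4)
  corr <- best_plane_correct(autocorrelation(m), sph)
  bp2 <- best_plane(corr$sphere)
  expect_lte(unname(bp2[1]), 6)
})

test_that("structure scores separate the canonical arrangements", {
  score_of <- function(kind) {
    m <- arrangement_ratemap(make_arrangement(kind, 400, seed = 3),
                             voxel_mm = 25)
    planar_symmetry(m, 33, 33)$scores
  }
  fcc <- score_of("FCC")
  col <- score_of("COL")
  rnd <- score_of("RND")
  expect_gt(fcc$chi_fcc, 0)
  expect_true(is.na(rnd$chi_fcc) || fcc$chi_fcc > rnd$chi_fcc)
  expect_gt(col$chi_col, fcc$chi_col)
  expect_gt(col$chi_col, 0.5)
  expect_equal(classify_configuration(col, method = "argmax"), "COL")
  rv <- c(rnd$chi_fcc, rnd$chi_hcp)
  expect_true(all(is.na(rv) | abs(rv) < 0.5))
})

test_that("hex azimuths of an axis-aligned FCC are 120 degrees apart", {
  sph <- sample_planes(fcc_ac(), 33, 33)
  geo <- plane_geometry(sph)
  expect_equal(mean(geo$hex_pairwise_diff), 120, tolerance = 0.05)
})

test_that("classification falls back sensibly", {
  sc <- structure(list(chi_fcc = NA_real_, chi_hcp = NA_real_,
                       chi_col = NA_real_), class = "vg_structure_scores")
  expect_equal(classify_configuration(sc, method = "argmax"), "uncategorized")
  sc2 <- structure(list(chi_fcc = 0.02, chi_hcp = -0.04, chi_col = 0.01),
                   class = "vg_structure_scores")
  expect_equal(classify_configuration(sc2, method = "argmax"), "RND")
  ref <- list(fcc = cbind(runif(10, 0.8, 1.2), runif(10, -0.1, 0.1),
                          runif(10, -0.1, 0.1)),
              rnd = cbind(runif(10, -0.1, 0.1), runif(10, -0.1, 0.1),
                          runif(10, -0.1, 0.1)))
  sc3 <- structure(list(chi_fcc = 1.0, chi_hcp = 0, chi_col = 0),
                   class = "vg_structure_scores")
  expect_equal(classify_configuration(sc3, ref, method = "hull"), "FCC")
  expect_equal(classify_configuration(sc3, ref, method = "region"), "FCC")
  sc4 <- structure(list(chi_fcc = 5, chi_hcp = 5, chi_col = 5),
                   class = "vg_structure_scores")
  expect_equal(classify_configuration(sc4, ref, method = "hull"),
               "uncategorized")
})
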