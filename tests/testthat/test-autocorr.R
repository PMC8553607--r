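brute_autocorr <- function(a, tx, ty, tz, min_overlap = 20) {
  d <- dim(a)
  A <- B <- numeric(0)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    x2 <- x - tx; y2 <- y - ty; z2 <- z - tz
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
      next
    if (is.na(a[x, y, z]) || is.na(a[x2, y2, z2])) next
    A <- c(A, a[x, y, z]); B <- c(B, a[x2, y2, z2])
  }
  if (length(A) < min_overlap) return(NA_real_)
  suppressWarnings(cor(A, B))
}

test_that("both autocorrelation paths match a brute-force oracle", {
  set.seed(31)
  a <- array(runif(9^3), dim = c(9, 9, 9))
  a[sample(729, 70)] <- NA
  acd <- autocorrelation(a, method = "direct")
  acf_ <- autocorrelation(a, method = "fft")
  expect_equal(acd$r[9, 9, 9], 1, tolerance = 1e-12)
  for (k in 1:20) {
    tau <- c(sample(-8:8, 1), sample(-8:8, 1), sample(-8:8, 1))
    o <- brute_autocorr(a, tau[1], tau[2], tau[3])
    idx <- tau + 9
    for (ac in list(acd, acf_)) {
      got <- ac$r[idx[1], idx[2], idx[3]]
      if (is.na(o)) expect_true(is.na(got))
      else expect_equal(got, o, tolerance = 1e-10)
    }
    # symmetry r(tau) = r(-tau)
    mir <- 18 - idx
    a1 <- acd$r[idx[1], idx[2], idx[3]]
    a2 <- acd$r[mir[1], mir[2], mir[3]]
    if (is.na(a1)) expect_true(is.na(a2))
    else expect_equal(a1, a2, tolerance = 1e-10)
  }
})

test_that("a cosine map has a cosine autocorrelation", {
  L <- 20
  x <- (1:60 - 0.5)
  m <- array(rep(cos(2 * pi * x / L), 4), dim = c(60, 2, 2))
  ac <- autocorrelation(m, min_overlap = 40)
  ctr <- ac$center
  lags <- 0:15
  got <- ac$r[ctr[1] + lags, ctr[2], ctr[3]]
  expect_equal(got, cos(2 * pi * lags / L), tolerance = 0.05)
})

test_that("constant maps are rejected", {
  expect_error(autocorrelation(array(2, dim = c(5, 5, 5))), "constant")
})

test_that("central peak radius matches a constructed sphere", {
  d <- c(21L, 21L, 21L)
  co <- arrayInd(seq_len(prod(d)), d)
  dist <- sqrt(rowSums(sweep(co, 2, c(11, 11, 11))^2))
  fake <- list(r = array(ifelse(dist <= 5, 0.9, -0.2), dim = d),
               m = array(1000L, dim = d), lag_voxel_cm = 2,
               center = c(11L, 11L, 11L))
  class(fake) <- "vg_autocorr"
  expect_equal(central_peak_radius(fake), 5 * 2, tolerance = 0.1)
})

test_that("field radius grows with the field width sigma", {
  radii <- vapply(c(1.5, 2, 3), function(sig) {
    m <- arrangement_ratemap(make_arrangement("FCC", 450), voxel_mm = 970 / 21,
                             sigma = sig)
    central_peak_radius(autocorrelation(m))
  }, numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("expanding-sphere spacing recovers the generator spacing", {
  for (kind in c("FCC", "HCP", "RND")) {
    m <- arrangement_ratemap(make_arrangement(kind, 400, seed = 2),
                             voxel_mm = 970 / 21)
    sp <- grid_spacing(autocorrelation(m))
    if (kind != "RND")
      expect_equal(sp$d * 10, 400, tolerance = 0.12)
  }
  # invariant to a 30-degree rotation within one shell
  m0 <- arrangement_ratemap(make_arrangement("FCC", 400), voxel_mm = 970 / 31)
  mr <- arrangement_ratemap(make_arrangement("FCC", 400), voxel_mm = 970 / 31,
                            rotation = list(axis = c(0.3, 0.6, 0.74),
                                            angle = 30))
  d0 <- grid_spacing(autocorrelation(m0))$d
  dr <- grid_spacing(autocorrelation(mr))$d
  expect_lte(abs(d0 - dr), 970 / 31 / 10 * 1.5)
})

test_that("a single central blob yields no spacing estimate", {
  d <- c(21L, 21L, 21L)
  co <- arrayInd(seq_len(prod(d)), d)
  dist <- sqrt(rowSums(sweep(co, 2, c(11, 11, 11))^2))
  fake <- list(r = array(exp(-0.5 * (dist / 3)^2), dim = d),
               m = array(1000L, dim = d), lag_voxel_cm = 2,
               center = c(11L, 11L, 11L))
  class(fake) <- "vg_autocorr"
  expect_true(is.na(grid_spacing(fake)$d))
})

test_that("midlines separate columnar from compact structure", {
  mc <- arrangement_ratemap(make_arrangement("COL", 350), voxel_mm = 970 / 21)
  ac <- autocorrelation(mc)
  prof <- midline_profiles(ac)
  ctr <- ac$center
  expect_equal(prof$z[ctr[3]], 1, tolerance = 1e-9)
  expect_gt(min(prof$z, na.rm = TRUE), 0.8)        # columns: flat high z line
  expect_lt(min(prof$x, na.rm = TRUE), 0.3)        # peaked x line
  expect_equal(prof$x, rev(prof$x), tolerance = 1e-9)
})

test_that("vertical self-similarity peaks at the layer-repeat distance", {
  mf <- arrangement_ratemap(make_arrangement("FCC", 320), voxel_mm = 970 / 31)
  spc <- grid_spacing(autocorrelation(mf))
  vss <- vertical_self_similarity(mf, spc$d)
  expect_equal(vss$r[1], 1, tolerance = 1e-9)
  # FCC repeats its identical layer every 3 close-packed layer steps
  pk <- attr(vss, "peaks")
  expect_true(any(abs(pk - 3 * 0.816) < 0.35))

  mcol <- arrangement_ratemap(make_arrangement("COL", 320), voxel_mm = 970 / 31)
  vc <- vertical_self_similarity(mcol, spc$d)
  expect_gt(min(vc$r, na.rm = TRUE), 0.95)
})

test_that("anisotropy correction spheres a stretched peak and is idempotent", {
  ac <- fcc_ac()
  # stretch the autocorrelation 1.5x along z by resampling
  d <- dim(ac$r)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  src_z <- (g[, 3] - ac$center[3]) / 1.5 + ac$center[3]
  stretched <- ac
  stretched$r <- array(volgrid:::cpp_interp3(ac$r, volgrid:::dims3(ac$r),
                                             g[, 1], g[, 2], src_z),
                       dim = d)
  corr <- anisotropy_correct(stretched)
  expect_equal(unname(corr$meta_scale[3] / corr$meta_scale[1]), 1.5,
               tolerance = 0.25)
  reg <- volgrid:::central_region(corr)
  ext <- apply(which(reg, arr.ind = TRUE), 2, function(i) diff(range(i)))
  expect_lte(max(ext) / max(1, min(ext)), 1.6)
  twice <- anisotropy_correct(corr)
  expect_true(all(abs(twice$meta_scale - 1) < 0.3))
})
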