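test_that("close-packed layer geometry follows the stacking rules", {
  for (S in c(250, 300, 450)) {
    hcp <- make_arrangement("HCP", S)
    zs <- sort(unique(round(hcp$points[, 3], 9)))
    expect_equal(diff(zs), rep(sqrt(6) / 3 * S, length(zs) - 1),
                 tolerance = 1e-9)
    # identical lateral offsets repeat with period 2 (ABA stacking)
    offs <- tapply(round(hcp$points[, 2] %% (sqrt(3) * S), 6), hcp$layer,
                   min)
    expect_equal(unname(offs[seq(1, length(offs) - 2)]),
                 unname(offs[seq(3, length(offs))]))
    expect_gt(length(unique(round(offs, 6))), 1)

    fcc <- make_arrangement("FCC", S)
    offs_f <- tapply(round(fcc$points[, 2] %% (sqrt(3) * S), 6), fcc$layer,
                     min)
    if (length(offs_f) >= 4)
      expect_equal(unname(offs_f[1]), unname(offs_f[4]))
    expect_equal(length(unique(round(offs_f[1:min(3, length(offs_f))], 6))),
                 min(3, length(offs_f)))
  }
})

test_that("in-plane nearest-neighbour distance equals the hexagon side", {
  arr <- make_arrangement("HCP", 300)
  lay0 <- arr$points[arr$layer == 0, 1:2, drop = FALSE]
  d <- as.matrix(dist(lay0))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(300, nrow(lay0)),
               tolerance = 1e-9)
})

test_that("random arrangements match the HCP point count and reproduce", {
  hcp <- make_arrangement("HCP", 350)
  r1 <- make_arrangement("RND", 350, seed = 42)
  r2 <- make_arrangement("RND", 350, seed = 42)
  expect_equal(nrow(r1$points), nrow(hcp$points))
  expect_identical(r1$points, r2$points)
  box <- apply(hcp$points, 2, range)
  expect_true(all(r1$points >= matrix(box[1, ], nrow(r1$points), 3,
                                      byrow = TRUE)))
  expect_true(all(r1$points <= matrix(box[2, ], nrow(r1$points), 3,
                                      byrow = TRUE)))
})

test_that("an undersized extent is rejected", {
  expect_error(make_arrangement("HCP", 500, extent = c(300, 300, 300)),
               "extent")
})

test_that("arrangement rate maps follow the Gaussian distance profile", {
  arr <- make_arrangement("FCC", 400)
  m <- arrangement_ratemap(arr, voxel_mm = 25, sigma = 2)
  expect_equal(max(m$rate, na.rm = TRUE), 1, tolerance = 1e-9)
  # a voxel two voxels (one sigma) off a field centre reads exp(-0.5)
  d <- dim(m$rate)
  ctr <- (d * 25) / 2
  i0 <- which.min(rowSums(sweep(arr$points, 2, ctr)^2))
  v0 <- pmax(1, pmin(ceiling(arr$points[i0, ] / 25), d))
  expect_equal(m$rate[v0[1], v0[2], v0[3]], 1, tolerance = 1e-9)
  shifted <- m$rate[v0[1] + 2, v0[2], v0[3]]
  expect_lte(abs(shifted - exp(-0.5)), 0.06)
})

test_that("rotation approximately preserves the value distribution", {
  m0 <- arrangement_ratemap(make_arrangement("FCC", 400), voxel_mm = 25)
  mr <- arrangement_ratemap(make_arrangement("FCC", 400), voxel_mm = 25,
                            rotation = list(axis = c(0, 0, 1), angle = 30))
  q0 <- quantile(m0$rate, c(0.5, 0.9, 0.99))
  qr <- quantile(mr$rate, c(0.5, 0.9, 0.99))
  expect_equal(unname(qr), unname(q0), tolerance = 0.15)
  expect_equal(max(mr$rate), 1, tolerance = 0.05)
})
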