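as_voi <- function(values, spacing = c(1, 1, 1)) {
  n <- length(values)
  vol <- suv_volume(array(values, c(n, 1, 1)), spacing)
  list(vol = vol, mask = voi_mask(array(TRUE, c(n, 1, 1)), spacing))
}

test_that("SUV statistics on a constant VOI all equal the constant", {
  vol <- suv_volume(array(4.2, c(9, 9, 9)), c(1, 1, 1))
  mask <- voi_mask(array(TRUE, c(9, 9, 9)), c(1, 1, 1))
  st <- suv_statistics(vol, mask)
  expect_equal(st$SUV_max, 4.2)
  expect_equal(st$SUV_mean, 4.2)
  expect_equal(st$SUV_peak, 4.2, tolerance = 1e-9)
  expect_equal(local_intensity_peak(vol, mask), 4.2, tolerance = 1e-9)
})

test_that("SUV_peak of a single hot voxel is the hot value over the sphere count", {
  d <- c(21, 21, 21)
  a <- array(0, d)
  a[11, 11, 11] <- 10
  vol <- suv_volume(a, c(1, 1, 1))
  mask <- voi_mask(a > 0, c(1, 1, 1))
  # enumerate the 6.2 mm sphere at 1 mm spacing by brute force
  n_sphere <- 0
  for (dx in -7:7) for (dy in -7:7) for (dz in -7:7) {
    if (sqrt(dx^2 + dy^2 + dz^2) <= 6.2) n_sphere <- n_sphere + 1
  }
  st <- suv_statistics(vol, mask)
  expect_equal(st$SUV_max, 10)
  expect_equal(st$SUV_peak, 10 / n_sphere, tolerance = 1e-9)
  expect_equal(local_intensity_peak(vol, mask), 10 / n_sphere,
               tolerance = 1e-9)
})

test_that("sphere means match the enumeration oracle off-centre too", {
  set.seed(31)
  d <- c(15, 15, 15)
  arr <- array(runif(prod(d)), d)
  vol <- suv_volume(arr, c(1.5, 1.5, 2))
  mask <- array(FALSE, d)
  mask[6:9, 6:9, 6:9] <- TRUE
  mask <- voi_mask(mask, c(1.5, 1.5, 2))
  lip <- local_intensity_peak(vol, mask)
  v <- arr
  v[!mask$data] <- -Inf
  centre <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_equal(lip, oracle_sphere_mean(arr, c(1.5, 1.5, 2), centre, 6.2),
               tolerance = 1e-9)
})

test_that("intensity statistics match direct formulas", {
  x1 <- as_voi(c(1, 1, 1, 1))
  f1 <- intensity_features(x1$vol, x1$mask)
  expect_equal(f1$ID_Range, 0)
  expect_equal(f1$ID_CoefficientOfVariation, 0)
  expect_equal(f1$ID_Energy, 4)

  x2 <- as_voi(c(0, 10))
  f2 <- intensity_features(x2$vol, x2$mask)
  expect_equal(f2$ID_Range, 10)
  expect_equal(f2$ID_Median, 5)
  expect_equal(f2$ID_RootMeanSquare, sqrt(50))

  for (vals in list(c(1, 2, 3, 4, 10),
                    runif(40, 0, 12),
                    rlnorm(25))) {
    xi <- as_voi(vals)
    expect_named_list_equal(intensity_features(xi$vol, xi$mask),
                            oracle_intensity(vals), tolerance = 1e-10)
  }
})

test_that("intensity statistics scale as dictated by their definitions", {
  set.seed(32)
  vals <- runif(50, 1, 9)
  a <- intensity_features(as_voi(vals)$vol, as_voi(vals)$mask)
  b <- intensity_features(as_voi(3 * vals)$vol, as_voi(3 * vals)$mask)
  expect_equal(b$ID_Range, 3 * a$ID_Range)
  expect_equal(b$ID_MeanAbsoluteDeviation, 3 * a$ID_MeanAbsoluteDeviation)
  expect_equal(b$ID_CoefficientOfVariation, a$ID_CoefficientOfVariation)
  expect_equal(b$ID_QuartileCoefficientOfDispersion,
               a$ID_QuartileCoefficientOfDispersion)
})

test_that("IVH features follow the fractional-intensity definitions", {
  const <- as_voi(rep(2.5, 20))
  fc <- ivh_features(const$vol, const$mask)
  expect_equal(fc$IVH_VolumeIntFract_90, 1)
  expect_equal(fc$IVH_AreaUnderIVHCurve, 1)

  half <- as_voi(rep(c(0, 10), each = 10))
  fh <- ivh_features(half$vol, half$mask)
  expect_equal(fh$IVH_VolumeIntFract_90, 0.5)

  ramp <- as_voi(seq(0, 1, length.out = 200))
  fr <- ivh_features(ramp$vol, ramp$mask)
  expect_equal(fr$IVH_AreaUnderIVHCurve, 0.5, tolerance = 0.01)
  # volume fraction at threshold is monotone in the threshold
  v85 <- ivh_features(ramp$vol, ramp$mask, volume_threshold = 0.85)
  v95 <- ivh_features(ramp$vol, ramp$mask, volume_threshold = 0.95)
  expect_gte(v85$IVH_VolumeIntFract_90, fr$IVH_VolumeIntFract_90)
  expect_gte(fr$IVH_VolumeIntFract_90, v95$IVH_VolumeIntFract_90)
})

test_that("fixed-bin-number discretization maps boundaries as specified", {
  x <- as_voi(0:31)
  disc <- discretize_fbn(x$vol, x$mask, 32)
  expect_identical(as.vector(disc$levels), 1:32)

  # min maps to level 1, max to the top bin for generic data
  y <- as_voi(c(2, 3, 9, 9, 4))
  dy <- discretize_fbn(y$vol, y$mask, 32)
  expect_equal(dy$levels[1, 1, 1], 1L)
  expect_equal(max(dy$levels, na.rm = TRUE), 32L)

  z <- as_voi(rep(7, 6))
  expect_true(all(discretize_fbn(z$vol, z$mask, 32)$levels == 1L))
})
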