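test_that("calibrated distances follow anisotropic pixel arithmetic", {
  cal32 <- scale_calibration(c(0.32, 0.32), 1)
  expect_equal(measure_distance(c(0, 0), c(0, 10), cal32), 3.2)
  cal1 <- scale_calibration(c(1, 1), 1)
  expect_equal(measure_distance(c(0, 0), c(3, 4), cal1), 5)
  caln <- scale_calibration(c(0.32, 1), 1)
  expect_equal(measure_distance(c(0, 0), c(3, 4), caln),
               sqrt((3 * 0.32)^2 + 4^2))
  expect_warning(d0 <- measure_distance(c(2, 2), c(2, 2), cal1), "identical")
  expect_equal(d0, 0)
  expect_error(scale_calibration(c(-1, 1), 1), "positive")
})

test_that("second-moment ellipse fit recovers the generating axes", {
  cal <- scale_calibration(c(0.32, 0.32), 1)
  f <- fit_nucleus_ellipse(raster_ellipse(15.5, 3.5, 0.32), cal)
  expect_lt(abs(f$major_um / 15.5 - 1), 0.02)
  expect_lt(abs(f$minor_um / 3.5 - 1), 0.02)

  # a circle has equal axes of the diameter, within a pixel
  circ <- raster_ellipse(10, 10, 0.5)
  fc <- fit_nucleus_ellipse(circ, scale_calibration(c(0.5, 0.5), 1))
  expect_lt(abs(fc$major_um - 10), 0.5)
  expect_lt(abs(fc$major_um - fc$minor_um), 0.5)

  expect_error(fit_nucleus_ellipse(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), cal),
               "5 pixels")
})

test_that("the ellipse fit is rotation-equivariant", {
  cal <- scale_calibration(c(0.32, 0.32), 1)
  f0 <- fit_nucleus_ellipse(raster_ellipse(12, 4, 0.32, theta = 0), cal)
  f37 <- fit_nucleus_ellipse(raster_ellipse(12, 4, 0.32, theta = 37 * pi / 180), cal)
  expect_lt(abs(f37$major_um - f0$major_um), 0.12 * 2)
  expect_lt(abs(f37$minor_um - f0$minor_um), 0.12 * 2)
  # orientation convention: angle from the x (column) axis, counter-clockwise
  # in image coordinates where theta rotated the ellipse by +37 degrees
  expect_lt(min(abs(f37$orientation_deg - c(-37, 37))), 1)
})

test_that("nucleus volumes voxel-count correctly with cohort statistics", {
  cal <- scale_calibration(c(0.32, 0.32), 1)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  nv <- nucleus_volume(one, cal)
  expect_equal(nv$volume_um3, 0.32 * 0.32 * 1)

  ell <- raster_ellipsoid(c(15.5, 3.5, 3.5), c(1, 0.32, 0.32))
  nve <- nucleus_volume(ell, cal)
  analytic <- 4 / 3 * pi * prod(c(15.5, 3.5, 3.5) / 2)
  expect_lt(abs(nve$volume_um3 / analytic - 1), 0.05)

  # five identical nuclei: sd 0, mean equal to the single volume
  five <- array(0L, c(3, 3, 15))
  for (k in 1:5) five[2, 2, 3 * k - 1] <- k
  nv5 <- nucleus_volume(five, cal)
  co <- attr(nv5, "cohort")
  expect_equal(co$n, 5L)
  expect_equal(co$sd_um3, 0)
  expect_equal(co$mean_um3, nv5$volume_um3[1])

  expect_error(nucleus_volume(array(0L, c(2, 2, 2)), cal), "labels")
})

test_that("vessel diameters derive from the centerline distance transform", {
  # thick tube: radius 25 voxels, isotropic
  t2 <- tube_mask(25, 12, vs = c(1, 1, 1), margin_um = 4)
  ctr <- (dim(t2)[2] + 1L) %/% 2L
  vd <- vessel_diameter(t2, c(6L, ctr, ctr), voxel_size_um = c(1, 1, 1))
  expect_lt(abs(vd$diameter_um / 50 - 1), 0.02)
  expect_match(vd$method, "centerline")

  # 1-voxel line: diameter is one voxel extent
  line <- array(FALSE, c(20, 7, 7))
  line[, 4, 4] <- TRUE
  vl <- vessel_diameter(line, c(10L, 4L, 4L), voxel_size_um = c(1, 1, 1))
  expect_equal(vl$diameter_um, 1)

  expect_error(vessel_diameter(line, c(1L, 1L, 1L), voxel_size_um = c(1, 1, 1)),
               "foreground")
})

test_that("all measurements scale linearly with the calibration", {
  mask <- raster_ellipse(12, 5, 0.4)
  f1 <- fit_nucleus_ellipse(mask, scale_calibration(c(0.4, 0.4), 1))
  f2 <- fit_nucleus_ellipse(mask, scale_calibration(c(0.8, 0.8), 2))
  expect_equal(f2$major_um, 2 * f1$major_um)
  expect_equal(f2$minor_um, 2 * f1$minor_um)

  expect_equal(measure_distance(c(1, 2), c(5, 9), scale_calibration(c(0.8, 0.8), 1)),
               2 * measure_distance(c(1, 2), c(5, 9), scale_calibration(c(0.4, 0.4), 1)))

  lab <- raster_ellipsoid(c(8, 4, 4), c(1, 0.5, 0.5))
  v1 <- nucleus_volume(lab, scale_calibration(c(0.5, 0.5), 1))
  v2 <- nucleus_volume(lab, scale_calibration(c(1, 1), 2))
  expect_equal(v2$volume_um3, 8 * v1$volume_um3)
})

test_that("morphometry records validate types and units", {
  r <- morphometry_record("n1", "nucleus_volume", 99.4, "um3", c(1, 2, 3), "test")
  expect_equal(r$unit, "um3")
  expect_error(morphometry_record("n1", "nucleus_volume", 99.4, "um"), "unit")
  expect_error(morphometry_record("d", "distance", -1, "um"), "positive")
  expect_error(morphometry_record("x", "not_a_type", 1, "um"), "feature_type")
})
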