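test_that("block reduction follows the documented rounding and max rules", {
  const <- build_pyramid(array(7L, c(8, 8, 8)), voxel_size_um = c(1, 1, 1),
                         max_coarse_vox = 4L)
  expect_true(all(const$levels[[2]]$data == 7L))
  expect_equal(const$levels[[2]]$shape, c(4L, 4L, 4L))

  vals <- build_pyramid(array(0:7, c(2, 2, 2)), voxel_size_um = c(1, 1, 1),
                        max_coarse_vox = 1L)
  # mean 28/8 = 3.5, rounded half-to-even
  expect_equal(as.integer(vals$levels[[2]]$data), 4L)

  mx <- build_pyramid(array(0:7, c(2, 2, 2)), voxel_size_um = c(1, 1, 1),
                      max_coarse_vox = 1L, method = "max")
  expect_equal(as.integer(mx$levels[[2]]$data), 7L)
})

test_that("level geometry follows the reduction factors", {
  vol <- array(sample.int(65535, 40 * 50 * 30, replace = TRUE) - 1L,
               c(40, 50, 30))
  pyr <- build_pyramid(vol, voxel_size_um = c(1, 0.32, 0.32),
                       max_coarse_vox = 8L)
  for (l in seq_along(pyr$levels)[-1]) {
    expect_equal(pyr$levels[[l]]$voxel_size_um,
                 pyr$levels[[l - 1]]$voxel_size_um * 2)
    expect_equal(pyr$levels[[l]]$shape,
                 as.integer(ceiling(pyr$levels[[l - 1]]$shape / 2)))
  }
})

test_that("level 0 reads back the input bit-exactly and means are stable", {
  set.seed(9)
  vol <- array(sample.int(65535, 32 * 48 * 40, replace = TRUE) - 1L,
               c(32, 48, 40))
  pyr <- build_pyramid(vol, voxel_size_um = c(1, 1, 1), max_coarse_vox = 8L)
  expect_identical(read_region(pyr, 0L, c(0L, 0L, 0L), dim(vol)), vol)
  for (l in seq_along(pyr$levels)[-1]) {
    expect_lt(abs(mean(pyr$levels[[l]]$data) - mean(vol)), 0.5 * (l - 1) + 0.5)
  }
  mx <- build_pyramid(vol, voxel_size_um = c(1, 1, 1), max_coarse_vox = 8L,
                      method = "max")
  for (l in seq_along(mx$levels)) expect_equal(max(mx$levels[[l]]$data), max(vol))
})

test_that("region reads match voxel-wise access and handle degenerate shapes", {
  set.seed(10)
  vol <- array(sample.int(65535, 30 * 30 * 30, replace = TRUE) - 1L, c(30, 30, 30))
  pyr <- build_pyramid(vol, voxel_size_um = c(1, 1, 1),
                       chunk_shape_vox = c(16L, 16L, 16L))
  # straddles the chunk boundary at index 16
  reg <- read_region(pyr, 0L, c(10L, 12L, 14L), c(10L, 8L, 9L))
  expect_identical(reg, vol[11:20, 13:20, 15:23])
  empty <- read_region(pyr, 0L, c(0L, 0L, 0L), c(0L, 5L, 5L))
  expect_equal(dim(empty), c(0L, 5L, 5L))
  expect_error(read_region(pyr, 0L, c(25L, 0L, 0L), c(10L, 5L, 5L)), "origin")
})

test_that("stored reads are independent of chunk shape", {
  set.seed(11)
  vol <- array(sample.int(65535, 24 * 40 * 36, replace = TRUE) - 1L, c(24, 40, 36))
  p1 <- build_pyramid(vol, voxel_size_um = c(1, 1, 1), chunk_shape_vox = c(8L, 8L, 8L))
  p2 <- build_pyramid(vol, voxel_size_um = c(1, 1, 1), chunk_shape_vox = c(16L, 32L, 5L))
  d1 <- file.path(tempdir(), "pyr_a"); d2 <- file.path(tempdir(), "pyr_b")
  write_pyramid(p1, d1); write_pyramid(p2, d2)
  o1 <- open_pyramid(d1); o2 <- open_pyramid(d2)
  expect_identical(read_region(o1, 0L, c(3L, 5L, 2L), c(15L, 20L, 30L)),
                   read_region(o2, 0L, c(3L, 5L, 2L), c(15L, 20L, 30L)))
  expect_identical(read_region(o1, 0L, c(0L, 0L, 0L), dim(vol)), vol)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("resampling at the native voxel is an identity copy", {
  vol <- array(sample.int(65535, 16 * 20 * 20, replace = TRUE) - 1L, c(16, 20, 20))
  pyr <- build_pyramid(vol, voxel_size_um = c(1, 0.5, 0.5))
  out <- resample_to_voxel(pyr, c(1, 0.5, 0.5))
  expect_equal(as.integer(out), as.integer(vol))
  expect_error(resample_to_voxel(pyr, c(0.5, 0.5, 0.5)), "upsampling")
})

test_that("trilinear resampling preserves a linear intensity ramp", {
  # f(x) = 100 x along the x axis
  nz <- 8; ny <- 8; nx <- 100
  ramp <- array(rep(100 * (0:(nx - 1)), each = nz * ny), c(nz, ny, nx))
  pyr <- build_pyramid(ramp, voxel_size_um = c(1, 1, 1),
                       max_coarse_vox = 512L)
  target <- c(2, 2, 2.5)
  out <- resample_to_voxel(pyr, target)
  expected <- 100 * (0:(dim(out)[3] - 1)) * 2.5    # analytic ramp at samples
  got <- out[1, 1, ]
  expect_lt(max(abs(got - expected)), 0.5 + 1e-9)
})

test_that("display-voxel resampling uses the ceiling shape convention", {
  # 100 x 320 x 320 at (1, 0.32, 0.32) um -> 10 um display grid
  vol <- array(0L, c(100, 320, 320))
  pyr <- build_pyramid(vol, voxel_size_um = c(1, 0.32, 0.32),
                       max_coarse_vox = 512L)
  out <- resample_to_voxel(pyr, c(10, 10, 10))
  expect_equal(dim(out), c(10L, 11L, 11L))   # ceil(100/10), ceil(102.4/10)
  expect_equal(attr(out, "voxel_size_um"), c(10, 10, 10))
})
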