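test_that("a thickness-one projection is the slice itself", {
  set.seed(20)
  vol <- array(sample.int(65535, 10 * 12 * 14, replace = TRUE) - 1L, c(10, 12, 14))
  mip <- max_projection(vol, "axial", 4L, 1L)
  sl <- vol[4, , ]; dim(sl) <- c(12, 14)
  expect_equal(unclass(mip)[,], sl, ignore_attr = TRUE)
})

test_that("projections agree with the slice-by-slice maximum oracle", {
  set.seed(21)
  vol <- array(sample.int(65535, 9 * 11 * 13, replace = TRUE) - 1L, c(9, 11, 13))
  for (ax in c("axial", "coronal", "sagittal")) {
    ai <- switch(ax, axial = 1L, coronal = 2L, sagittal = 3L)
    mip <- max_projection(vol, ax)
    oracle <- apply(vol, setdiff(1:3, ai), max)
    expect_equal(unclass(mip)[,], oracle, ignore_attr = TRUE)
  }
  # element-wise dominance over every slice
  mip <- unclass(max_projection(vol, "axial"))
  for (z in 1:9) {
    sl <- vol[z, , ]; dim(sl) <- c(11, 13)
    expect_true(all(mip >= sl))
  }
  expect_error(max_projection(vol, "axial", 8L, 5L), "slab")
})

test_that("projection is invariant under slice permutation", {
  set.seed(22)
  vol <- array(sample.int(65535, 8 * 10 * 10, replace = TRUE) - 1L, c(8, 10, 10))
  perm <- sample(8)
  expect_equal(unclass(max_projection(vol, "axial")),
               unclass(max_projection(vol[perm, , ], "axial")))
})

test_that("channel merging follows the fuchsia/green arithmetic", {
  myo <- matrix(c(0, 65535, 65535, 0), 2, 2)
  vasc <- matrix(c(0, 0, 65535, 65535), 2, 2)
  rgbimg <- merge_channels(myo, vasc)
  expect_equal(rgbimg[1, 1, ], c(0L, 0L, 0L))          # both zero -> black
  expect_equal(rgbimg[2, 1, ], c(255L, 0L, 255L))      # myo only -> fuchsia
  expect_equal(rgbimg[1, 2, ], c(255L, 255L, 255L))    # both max -> white
  expect_equal(rgbimg[2, 2, ], c(0L, 255L, 0L))        # vasc only -> green

  # vasc all zero: a pure fuchsia rendering of myo
  z <- matrix(0, 2, 2)
  pure <- merge_channels(myo, z)
  expect_true(all(pure[, , 2] == 0))
  expect_equal(pure[, , 1], pure[, , 3])

  # symmetric under swapping channels together with their colors
  sw <- merge_channels(vasc, myo, myo_color = c(0, 255, 0),
                       vasc_color = c(255, 0, 255))
  expect_equal(unclass(sw), unclass(rgbimg))

  expect_error(merge_channels(myo, matrix(0, 3, 2)), "shape")
})

test_that("depth coding of a single slice uses the first colormap color", {
  img <- matrix(c(0, 1, 1, 0), 2, 2)
  dc <- depth_code(array(img, c(1, 2, 2)), threshold = 0.5)
  cmap <- dc$colormap
  expect_equal(nrow(cmap), 1)
  fg <- !is.na(dc$slice_of_origin)
  expect_true(all(dc$slice_of_origin[fg] == 1L))
  for (ch in 1:3) expect_true(all(dc$rgb[, , ch][fg] == cmap[1, ch]))
  expect_true(all(dc$rgb[, , 1][!fg] == 0))
})

test_that("stacking order resolves multi-hit pixels as specified", {
  # pixel (1,1) foreground in slices 1 and 3 only
  st <- array(0, c(3, 2, 2))
  st[1, 1, 1] <- 1; st[3, 1, 1] <- 1
  st[2, 2, 2] <- 1
  last <- depth_code(st, threshold = 0.5, order = "last_hit")
  expect_equal(last$slice_of_origin[1, 1], 3L)
  expect_equal(last$rgb[1, 1, ], unname(last$colormap[3, ]))
  first <- depth_code(st, threshold = 0.5, order = "first_hit")
  expect_equal(first$slice_of_origin[1, 1], 1L)
  expect_equal(first$rgb[1, 1, ], unname(first$colormap[1, ]))
  expect_equal(first$slice_of_origin[2, 2], 2L)
})

test_that("depth coding matches the per-pixel scan oracle on random stacks", {
  set.seed(23)
  for (i in 1:50) {
    st <- array(stats::rbinom(16 * 8 * 8, 1, 0.3), c(16, 8, 8))
    for (ord in c("last_hit", "first_hit")) {
      dc <- depth_code(st, threshold = 0.5, order = ord)
      expect_identical(dc$slice_of_origin, depth_code_oracle(st, 0.5, ord))
    }
  }
})

test_that("only assigned slice colors appear, never interpolated ones", {
  set.seed(24)
  st <- array(stats::rbinom(10 * 6 * 6, 1, 0.4), c(10, 6, 6))
  dc <- depth_code(st, threshold = 0.5)
  fg <- which(!is.na(dc$slice_of_origin))
  seen <- paste(dc$rgb[, , 1][fg], dc$rgb[, , 2][fg], dc$rgb[, , 3][fg])
  allowed <- paste(dc$colormap[, 1], dc$colormap[, 2], dc$colormap[, 3])
  expect_true(all(seen %in% allowed))
})

test_that("an out-of-range threshold yields an all-background warning", {
  st <- array(runif(4 * 5 * 5), c(4, 5, 5))
  expect_warning(dc <- depth_code(st, threshold = 2), "background")
  expect_true(all(is.na(dc$slice_of_origin)))
})

test_that("a tube descending in z gets monotone depth colors along its path", {
  # diagonal bright tube: slice z has foreground at column z
  k <- 12
  st <- array(0, c(k, 4, k))
  for (z in 1:k) st[z, , z] <- 1
  dc <- depth_code(st, threshold = 0.5)
  path_origin <- dc$slice_of_origin[2, ]
  expect_true(all(diff(path_origin) > 0))
  # hue decreases monotonically blue -> red along depth
  hues <- apply(dc$colormap, 1, function(co) grDevices::rgb2hsv(co[1], co[2], co[3])[1])
  expect_true(all(diff(hues) < 0))
})
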