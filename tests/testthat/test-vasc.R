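test_that("noise-free segmentation at a mid threshold recovers the truth mask", {
  spec <- tiny_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  thr <- (spec$background_level + spec$foreground_level) / 2
  vm <- segment_threshold(ph$channel_vasc, thr, voxel_size_um = spec$voxel_size_um)
  expect_identical(as.vector(vm$mask), as.vector(ph$truth$vessel_mask))
  expect_equal(vm$threshold_used, thr)
})

test_that("a threshold above the global max warns and returns an empty mask", {
  vol <- array(100L, c(5, 5, 5))
  expect_warning(vm <- segment_threshold(vol, 1e6), "background")
  expect_false(any(vm$mask))
})

test_that("auto-threshold segmentation under 5% noise reaches Dice >= 0.95", {
  spec <- tiny_phantom_spec(noise_sd = 0.05 * (20000 - 1000), seed = 8L)
  ph <- generate_phantom(spec)
  vm <- segment_threshold(ph$channel_vasc, "auto", min_component_vox = 27L,
                          voxel_size_um = spec$voxel_size_um)
  truth <- ph$truth$vessel_mask
  dice <- 2 * sum(vm$mask & truth) / (sum(vm$mask) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("manual edits apply in order, invert, and replay from the log", {
  spec <- tiny_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  vm <- segment_threshold(ph$channel_vasc, 10000, voxel_size_um = spec$voxel_size_um)

  expect_identical(apply_manual_edits(vm, list())$mask, vm$mask)

  region <- matrix(FALSE, dim(vm$mask)[2], dim(vm$mask)[3])
  region[5:10, 5:10] <- TRUE
  added <- apply_manual_edits(vm, list(list(z = 3L, op = "add", region = region)))
  expect_true(all(added$mask[3, 5:10, 5:10]))
  undone <- apply_manual_edits(added, list(list(z = 3L, op = "remove", region = region)))
  removed_back <- vm$mask
  removed_back[3, , ][region] <- FALSE
  expect_identical(undone$mask, removed_back)

  # an add is idempotent on re-application
  twice <- apply_manual_edits(added, list(list(z = 3L, op = "add", region = region)))
  expect_identical(twice$mask, added$mask)

  # replaying the accumulated log on the original reproduces the final mask
  replayed <- replay_edits(vm, undone$edit_log)
  expect_identical(replayed$mask, undone$mask)

  expect_error(apply_manual_edits(vm, list(list(z = 999L, op = "add", region = region))),
               "range")
})

test_that("tracing a straight tube reports an unbranched trunk", {
  tube <- tube_mask(4, 40)
  ctr <- (dim(tube)[2] + 1L) %/% 2L
  rpt <- trace_from_seed(tube, c(20L, ctr, ctr), voxel_size_um = c(1, 1, 1))
  expect_equal(rpt$branch_count, 0L)
  expect_equal(rpt$component_voxel_count, sum(tube))
  expect_identical(rpt$traced_mask, tube)
})

test_that("tracing stays inside the seeded component", {
  two <- array(FALSE, c(20, 30, 12))
  two[, 5:8, 5:8] <- TRUE
  two[, 22:25, 5:8] <- TRUE
  rpt <- trace_from_seed(two, c(10L, 6L, 6L), voxel_size_um = c(1, 1, 1))
  expect_true(all(!rpt$traced_mask[, 22:25, ]))
  expect_equal(rpt$component_voxel_count, 20L * 16L)
})

test_that("a background seed errors naming the nearest foreground voxel", {
  tube <- tube_mask(3, 10)
  expect_error(trace_from_seed(tube, c(5L, 1L, 1L), voxel_size_um = c(1, 1, 1)),
               "nearest foreground")
})

test_that("branch count is independent of the seed within a component", {
  spec <- tiny_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- ph$truth$vessel_mask
  idx <- which(m)
  set.seed(30)
  d <- dim(m)
  picks <- sample(idx, 3)
  counts <- vapply(picks, function(i) {
    s <- c((i - 1) %% d[1], ((i - 1) %/% d[1]) %% d[2],
           (i - 1) %/% (d[1] * d[2])) + 1L
    trace_from_seed(m, s, voxel_size_um = spec$voxel_size_um)$branch_count
  }, integer(1))
  expect_true(all(counts == counts[1]))
})

test_that("phantom tree branch count matches the ground-truth graph", {
  spec <- tiny_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- ph$truth$vessel_mask
  edt <- distance_transform(m, spec$voxel_size_um)
  k <- which.max(edt) - 1L
  d <- dim(m)
  seedv <- c(k %% d[1], (k %/% d[1]) %% d[2], k %/% (d[1] * d[2])) + 1L
  rpt <- trace_from_seed(m, seedv, voxel_size_um = spec$voxel_size_um)
  expect_equal(rpt$branch_count, ph$truth$vessel_graph$branch_count)
  expect_true(any(rpt$branches$is_trunk))
})

test_that("per-branch radii track the generating tube radii", {
  tree <- test_tree(c(47, 47, 47), trunk_radius_um = 4, branch_radius_um = 1.5)
  spec <- phantom_spec(volume_shape_vox = c(48L, 148L, 148L),
                       voxel_size_um = c(1, 0.32, 0.32),
                       vessel_tree = tree, noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- ph$truth$vessel_mask
  rpt <- trace_from_seed(m, c(24L, 74L, 74L), voxel_size_um = spec$voxel_size_um)
  br <- rpt$branches
  trunk_r <- max(br$mean_radius_um[br$is_trunk])
  side_r <- br$mean_radius_um[!br$is_trunk]
  expect_gt(trunk_r, 2.8)                  # trunk ~4 um
  expect_lt(abs(median(side_r) - 1.5), 0.8)
})
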