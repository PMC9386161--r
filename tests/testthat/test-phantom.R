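test_that("phantom spec validation enforces the geometric invariants", {
  expect_error(phantom_spec(volume_shape_vox = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(nucleus_axes_um = c(3, 5, 5)), "major")
  expect_error(phantom_spec(layer_boundaries_frac = c(0.6, 0.4)), "increasing")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("identical spec and seed give bit-identical volumes", {
  spec <- tiny_phantom_spec(seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$channel_myo, b$channel_myo)
  expect_identical(a$channel_vasc, b$channel_vasc)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
})

test_that("no vessels and no noise leave the vascular channel flat", {
  spec <- tiny_phantom_spec(vessel_tree = list(), noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_true(all(ph$channel_vasc == spec$background_level))
  expect_false(any(ph$truth$vessel_mask))
})

test_that("ground-truth nucleus volume matches the analytic ellipsoid", {
  # single nucleus of paper-scale axes at the acquisition voxel size
  spec <- phantom_spec(volume_shape_vox = c(32L, 220L, 220L),
                       vessel_tree = list(), noise_sd = 0,
                       disc_spacing_um = 31, myocyte_radius_um = 8)
  ph <- generate_phantom(spec)
  tab <- ph$truth$nucleus_table
  expect_gt(nrow(tab), 0)
  analytic <- 4 / 3 * pi * prod(spec$nucleus_axes_um / 2)   # ~99.4 um^3
  # an unclipped nucleus (the largest) voxel-counts to the analytic volume
  expect_lt(abs(max(tab$volume_um3) / analytic - 1), 0.05)
  # every nucleus voxel lies inside exactly one myocyte
  nl <- ph$truth$nucleus_label_volume
  ml <- ph$truth$myocyte_label_volume
  expect_true(all(ml[nl > 0] > 0))
  for (lb in unique(nl[nl > 0])) {
    expect_length(unique(ml[nl == lb]), 1)
  }
})

test_that("a single capillary-scale tube rasterizes at 2 um diameter", {
  # axis on the voxel lattice (11.84 = 37 * 0.32): the clean rasterization;
  # sub-voxel axis placement shifts the estimate by up to half a voxel
  tree <- vessel_branch(c(2, 11.84, 11.84), c(1, 0, 0), 40, 1)
  spec <- phantom_spec(volume_shape_vox = c(48L, 76L, 76L),
                       vessel_tree = tree, noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- ph$truth$vessel_mask
  expect_equal(max(label_components(m)), 1)     # one connected component
  vd <- vessel_diameter(m, c(24, 38, 38), voxel_size_um = spec$voxel_size_um)
  expect_lt(abs(vd$diameter_um - 2), 0.32 + 1e-9)
})

test_that("vessel mask equals the rasterization of the centerline tubes", {
  spec <- tiny_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  g <- ph$truth$vessel_graph
  d <- spec$volume_shape_vox
  vs <- spec$voxel_size_um
  P <- cbind((rep(seq_len(d[1]), times = d[2] * d[3]) - 1) * vs[1],
             (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 1) * vs[2],
             (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * vs[3])
  ref <- rep(FALSE, nrow(P))
  for (e in seq_len(nrow(g$edges))) {
    A <- unlist(g$nodes[g$edges$from[e], c("z_um", "y_um", "x_um")])
    B <- unlist(g$nodes[g$edges$to[e], c("z_um", "y_um", "x_um")])
    dseg <- heartvox:::capsule_distance(P, A, B)
    ref <- ref | (dseg <= g$edges$radius[e])
  }
  expect_identical(as.vector(ph$truth$vessel_mask), ref)
})

test_that("branches leaving the volume are clipped with a warning", {
  tree <- vessel_branch(c(10, 10, 10), c(0, 0, 1), 500, 2)
  spec <- tiny_phantom_spec(vessel_tree = tree, noise_sd = 0)
  expect_warning(generate_phantom(spec), "clipped")
})

test_that("strip emission covers the section and records true offsets", {
  sec <- matrix(seq_len(100 * 40), nrow = 40)
  vol <- array(sec, dim = c(1, 40, 100))

  one <- emit_strips(vol, 100L, 0L)
  expect_length(one$strips, 1)
  expect_identical(one$strips[[1]]$pixels, sec)

  two <- emit_strips(vol, 60L, 20L)
  expect_length(two$strips, 2)
  expect_identical(two$strips[[1]]$pixels, sec[, 1:60])
  expect_identical(two$strips[[2]]$pixels, sec[, 41:100])
  expect_equal(two$true_offsets$d_col, 40L)
  # re-abutting with the overlap removed reconstructs the section
  rebuilt <- cbind(two$strips[[1]]$pixels,
                   two$strips[[2]]$pixels[, 21:60])
  expect_identical(rebuilt, sec)

  disjoint <- emit_strips(vol, 50L, 0L)
  expect_identical(cbind(disjoint$strips[[1]]$pixels,
                         disjoint$strips[[2]]$pixels), sec)

  expect_warning(emit_strips(vol, 120L, 10L), "single strip")
  expect_error(emit_strips(vol, 20L, 20L), "overlap")
})

test_that("alternate strips carry the reversed-scan flag", {
  vol <- array(seq_len(1 * 20 * 90), dim = c(1, 20, 90))
  em <- emit_strips(vol, 40L, 15L)
  rev <- vapply(em$strips, function(s) s$scan_reversed, logical(1))
  expect_identical(rev, (seq_along(em$strips) %% 2) == 0)
})
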