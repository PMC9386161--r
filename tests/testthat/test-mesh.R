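test_that("a voxel ball yields a watertight mesh of the analytic volume", {
  m <- ball_mask(15L)
  mesh <- extract_surface(m, voxel_size_um = c(1, 1, 1))
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) / (4 / 3 * pi * 15^3) - 1), 0.05)
})

test_that("a single isolated voxel yields a small closed polyhedron", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  mesh <- extract_surface(m, smoothing_iterations = 2L, voxel_size_um = c(1, 1, 1))
  expect_true(is_watertight(mesh))
  expect_gt(nrow(mesh$triangles), 3)
  expect_error(extract_surface(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("a solid box mesh stays within one voxel of the box bounds", {
  m <- array(FALSE, c(20, 24, 28))
  m[6:15, 7:18, 9:20] <- TRUE
  mesh <- extract_surface(m, voxel_size_um = c(1, 1, 1))
  # box extents in um (0-based voxel centers)
  expect_gte(min(mesh$vertices[, 3]), 5 - 1.5)  # z
  expect_lte(max(mesh$vertices[, 3]), 14 + 1.5)
  expect_gte(min(mesh$vertices[, 2]), 6 - 1.5)  # y
  expect_lte(max(mesh$vertices[, 2]), 17 + 1.5)
  expect_gte(min(mesh$vertices[, 1]), 8 - 1.5)  # x
  expect_lte(max(mesh$vertices[, 1]), 19 + 1.5)
})

test_that("mean curvature matches the analytic sphere and outward sign", {
  vs <- c(0.5, 0.5, 0.5)
  mesh <- extract_surface(ball_mask(20L), voxel_size_um = vs)   # r = 10 um
  mesh <- vertex_curvature(mesh, "mean")
  expect_lt(abs(median(mesh$curvature) - 0.1), 0.01)   # 1/r within 10%
  # convex outward positive: the vast majority of vertices
  expect_gt(mean(mesh$curvature > 0), 0.9)
})

test_that("mid-cylinder mean curvature approximates half the inverse radius", {
  vs <- c(0.5, 0.5, 0.5)
  mesh <- extract_surface(tube_mask(5, 120L, vs = vs, offset_vox = c(0.5, 0.5)),
                          voxel_size_um = vs)
  mesh <- vertex_curvature(mesh, "mean")
  zmax <- 120 * 0.5
  mid <- mesh$vertices[, 3] > zmax * 0.35 & mesh$vertices[, 3] < zmax * 0.65
  expect_lt(abs(median(mesh$curvature[mid]) - 0.1), 0.015)  # 1/(2r), 15%
})

test_that("a flat plate has near-zero mean curvature away from its rim", {
  m <- array(FALSE, c(20, 40, 40))
  m[8:12, , ] <- TRUE
  mesh <- extract_surface(m, voxel_size_um = c(1, 1, 1))
  mesh <- vertex_curvature(mesh, "mean")
  interior <- mesh$vertices[, 1] > 10 & mesh$vertices[, 1] < 29 &
              mesh$vertices[, 2] > 10 & mesh$vertices[, 2] < 29
  expect_lt(median(abs(mesh$curvature[interior])), 0.01)
})

test_that("gaussian and principal curvature are consistent on a sphere", {
  vs <- c(0.5, 0.5, 0.5)
  mesh <- extract_surface(ball_mask(20L), voxel_size_um = vs)
  kg <- vertex_curvature(mesh, "gaussian")
  expect_lt(abs(median(kg$curvature) - 0.01), 0.004)   # 1/r^2
  kp <- vertex_curvature(mesh, "max_principal")
  expect_gt(median(kp$curvature), 0.05)
})

test_that("curvature colorization maps extremes to blue and red", {
  # synthetic two-value field on a tiny mesh
  mesh <- extract_surface(ball_mask(6L), smoothing_iterations = 5L,
                          voxel_size_um = c(1, 1, 1))
  n <- nrow(mesh$vertices)
  mesh$curvature <- rep(c(0, 1), length.out = n)
  mesh$curvature_kind <- "mean"
  col <- colorize_curvature(mesh)
  lows <- col$color[col$curvature == 0, , drop = FALSE]
  highs <- col$color[col$curvature == 1, , drop = FALSE]
  expect_true(all(lows[, 3] == 255 & lows[, 1] == 0))    # blue
  expect_true(all(highs[, 1] == 255 & highs[, 3] == 0))  # red

  mesh$curvature <- rep(0.5, n)
  expect_warning(colorize_curvature(mesh), "constant")

  expect_error(colorize_curvature(extract_surface(ball_mask(6L),
                                                  smoothing_iterations = 0L,
                                                  voxel_size_um = c(1, 1, 1))),
               "curvature")
})

test_that("thin branches color red relative to the thick trunk", {
  tree <- test_tree(c(47, 47, 47), trunk_radius_um = 5, branch_radius_um = 1.5,
                    n_side = 2)
  spec <- phantom_spec(volume_shape_vox = c(48L, 148L, 148L),
                       vessel_tree = tree, noise_sd = 0)
  ph <- generate_phantom(spec)
  mesh <- extract_surface(ph$truth$vessel_mask, voxel_size_um = spec$voxel_size_um)
  mesh <- colorize_curvature(vertex_curvature(mesh, "mean"))
  # distance from the trunk axis (y = x = 23.5 um) classifies vertices
  daxis <- sqrt((mesh$vertices[, 2] - 23.5)^2 + (mesh$vertices[, 1] - 23.5)^2)
  on_trunk <- daxis < 5.5
  on_branch <- daxis > 12
  expect_gt(mean(mesh$color[on_branch, 1]),  # red channel
            mean(mesh$color[on_trunk, 1]))
  expect_gt(median(vertex_curvature(mesh, "mean")$curvature[on_branch]),
            median(vertex_curvature(mesh, "mean")$curvature[on_trunk]))
})

test_that("the segmentation-surface-volume chain recovers tube volume", {
  # tube radius 3 in-plane voxels at the anisotropic acquisition sampling
  vs <- c(1, 0.32, 0.32)
  r_um <- 3 * 0.32
  tube <- tube_mask(r_um, 30L, vs = vs)
  # field presmoothing shrinks thin structures by ~ sigma^2 * curvature / 2;
  # for measurement, sigma is kept below ~1/3 of the thinnest radius
  mesh <- extract_surface(tube, presmooth_sigma_vox = 0.8, voxel_size_um = vs)
  analytic <- pi * r_um^2 * (30 * vs[1])
  expect_lt(abs(mesh_volume(mesh) / analytic - 1), 0.10)
})

test_that("mesh export writes valid PLY and OBJ files", {
  mesh <- extract_surface(ball_mask(5L), smoothing_iterations = 2L,
                          voxel_size_um = c(1, 1, 1))
  mesh <- colorize_curvature(vertex_curvature(mesh, "mean"))
  ply <- file.path(tempdir(), "m.ply")
  obj <- file.path(tempdir(), "m.obj")
  write_mesh(mesh, ply)
  write_mesh(mesh, obj)
  hl <- readLines(ply, n = 20)
  expect_equal(hl[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(mesh$vertices)), hl)))
  ol <- readLines(obj)
  expect_equal(sum(grepl("^v ", ol)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", ol)), nrow(mesh$triangles))
  unlink(c(ply, obj))
})
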