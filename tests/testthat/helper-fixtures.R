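# Fixture builders shared across test files. All geometry is generated in
# code; no data files.

# solid axis-aligned ball mask, isotropic unless vs given
ball_mask <- function(radius_vox, margin = 3L, vs = c(1, 1, 1)) {
  n <- 2L * (radius_vox + margin) + 1L
  ax <- seq_len(n) - (radius_vox + margin + 1L)
  m <- array(FALSE, c(n, n, n))
  for (z in seq_len(n)) for (y in seq_len(n))
    m[z, y, ] <- (ax[z]^2 + ax[y]^2 + ax^2) <= radius_vox^2
  m
}

# solid tube along z, circular cross-section of radius_um in the (y, x) plane;
# offset_vox places the axis off the lattice (the generic configuration --
# a lattice-aligned axis is a degenerate rasterization with mirror-symmetric
# terracing)
tube_mask <- function(radius_um, nz, vs = c(1, 1, 1), margin_um = 3,
                      offset_vox = c(0, 0)) {
  half <- ceiling((radius_um + margin_um) / vs[2])
  n <- 2L * half + 1L
  ax_y <- (seq_len(n) - half - 1L - offset_vox[1]) * vs[2]
  ax_x <- (seq_len(n) - half - 1L - offset_vox[2]) * vs[3]
  m <- array(FALSE, c(nz, n, n))
  for (y in seq_len(n))
    m[, y, ] <- matrix(ax_y[y]^2 + ax_x^2 <= radius_um^2, 1L)[rep(1L, nz), ]
  m
}

# rasterized 2D ellipse, full axes in um; generic sub-pixel center offset
# (a perfectly grid-aligned ellipse is a degenerate rasterization whose
# discretization errors are correlated across rows)
raster_ellipse <- function(major_um, minor_um, px_um, theta = 0,
                           offset_px = c(0.3, 0.7)) {
  n <- as.integer(ceiling(major_um / px_um) + 8L)
  cx <- n / 2 + offset_px[1]
  cy <- n / 2 + offset_px[2]
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  xr <- (g$c - cx) * px_um
  yr <- (g$r - cy) * px_um
  u <- xr * cos(theta) + yr * sin(theta)
  v <- -xr * sin(theta) + yr * cos(theta)
  matrix((u / (major_um / 2))^2 + (v / (minor_um / 2))^2 <= 1, n, n)
}

# rasterized 3D ellipsoid label volume (label 1), axes full lengths in um,
# z axis = first axis
raster_ellipsoid <- function(axes_um, vs) {
  half <- ceiling(axes_um / 2 / vs) + 3
  d <- as.integer(2 * half + 1)
  ctr <- (half + 1)
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  inside <- (((g$z - ctr[1]) * vs[1]) / (axes_um[1] / 2))^2 +
            (((g$y - ctr[2]) * vs[2]) / (axes_um[2] / 2))^2 +
            (((g$x - ctr[3]) * vs[3]) / (axes_um[3] / 2))^2 <= 1
  lab <- array(0L, d)
  lab[as.matrix(g)[inside, ]] <- 1L
  lab
}

# small fast phantom for module tests; the default tree is proportioned so
# skeleton endpoints are well defined at this scale
tiny_phantom_spec <- function(..., vessel_tree = NULL) {
  shape <- c(48L, 96L, 96L)
  if (is.null(vessel_tree))
    vessel_tree <- test_tree((shape - 1L) * c(1, 0.32, 0.32),
                             trunk_radius_um = 3, branch_radius_um = 1.2)
  phantom_spec(volume_shape_vox = shape, vessel_tree = vessel_tree, ...)
}

# a tree with a trunk and n side branches, proportions in the regime where
# skeleton endpoints are well defined (overhang > 3 x trunk radius)
test_tree <- function(extent_um, trunk_radius_um = 4, branch_radius_um = 1.5,
                      n_side = 3) {
  side <- lapply(seq_len(n_side), function(i) {
    ang <- (i - 1) * 2.1
    vessel_branch(NULL, c(0.2, sin(ang), cos(ang)),
                  length_um = min(extent_um[2:3]) * 0.3,
                  radius_um = branch_radius_um,
                  attach_frac = 0.3 + 0.4 * i / (n_side + 1))
  })
  vessel_branch(c(0.05 * extent_um[1], 0.5 * extent_um[2], 0.5 * extent_um[3]),
                c(1, 0, 0), 0.9 * extent_um[1], trunk_radius_um, side)
}

# brute-force depth-coding oracle: per-pixel scan over slices
depth_code_oracle <- function(stack, thr, order) {
  k <- dim(stack)[1]
  out <- matrix(NA_integer_, dim(stack)[2], dim(stack)[3])
  for (r in seq_len(dim(stack)[2])) for (c in seq_len(dim(stack)[3])) {
    hits <- which(stack[, r, c] >= thr)
    if (length(hits))
      out[r, c] <- if (order == "last_hit") max(hits) else min(hits)
  }
  out
}
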