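# Internal helpers shared across modules. All volumes in this package are
# numeric or integer 3D arrays in (z, y, x) dimension order; physical position
# of voxel (i, j, k) (1-based) is ((i-1), (j-1), (k-1)) * voxel_size_um.

`%||%` <- function(a, b) if (is.null(a)) b else a

U16_MAX <- 65535L

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clip_u16 <- function(x) {
  x[x < 0] <- 0
  x[x > U16_MAX] <- U16_MAX
  x
}

# round half-to-even (base round) then clip to the 16-bit range, keep dims
as_u16 <- function(x) {
  d <- dim(x)
  out <- as.integer(clip_u16(round(x)))
  dim(out) <- d
  out
}

check_volume <- function(vol, arg = "volume") {
  if (!(is.array(vol) && length(dim(vol)) == 3))
    stop(sprintf("`%s` must be a 3D array in (z, y, x) order", arg), call. = FALSE)
  invisible(vol)
}

check_triple <- function(x, arg, positive = TRUE) {
  if (length(x) != 3 || !is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be a numeric triple (z, y, x)", arg), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be positive", arg), call. = FALSE)
  invisible(as.numeric(x))
}

#' Global Otsu threshold of an intensity array
#'
#' Thin wrapper around [EBImage::otsu()] applied to the pooled histogram of
#' all values (EBImage computes per-frame thresholds; here the whole array is
#' one sample).
#' @noRd
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  img <- EBImage::Image(matrix((v - lo) / (hi - lo), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(seq(-r, r), 0, sigma)
  w / sum(w)
}

index_axis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable Gaussian smoothing with replicated edges; sigma per axis in voxels
smooth_gauss3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    k <- gauss_kernel1d(s)
    r <- (length(k) - 1L) / 2L
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * index_axis(a, axis, idx)
    }
    a <- out
  }
  a
}

# trilinear interpolation at continuous 0-based voxel coordinates (clamped to
# the volume domain, i.e. replicated edges)
trilinear_sample <- function(vol, z, y, x) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  z <- pmin(pmax(z, 0), nz - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  z1 <- pmin(z0 + 1, nz - 1); y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  lin <- function(zz, yy, xx) zz + nz * (yy + ny * xx) + 1
  v <- as.numeric(vol)
  (1 - fz) * (1 - fy) * (1 - fx) * v[lin(z0, y0, x0)] +
  (1 - fz) * (1 - fy) * fx       * v[lin(z0, y0, x1)] +
  (1 - fz) * fy       * (1 - fx) * v[lin(z0, y1, x0)] +
  (1 - fz) * fy       * fx       * v[lin(z0, y1, x1)] +
  fz       * (1 - fy) * (1 - fx) * v[lin(z1, y0, x0)] +
  fz       * (1 - fy) * fx       * v[lin(z1, y0, x1)] +
  fz       * fy       * (1 - fx) * v[lin(z1, y1, x0)] +
  fz       * fy       * fx       * v[lin(z1, y1, x1)]
}

# distance (um) from points P (n x 3, columns z,y,x um) to segment A-B (um)
capsule_distance <- function(P, A, B) {
  d <- B - A
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(sqrt((P[, 1] - A[1])^2 + (P[, 2] - A[2])^2 + (P[, 3] - A[3])^2))
  }
  t <- ((P[, 1] - A[1]) * d[1] + (P[, 2] - A[2]) * d[2] + (P[, 3] - A[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((P[, 1] - (A[1] + t * d[1]))^2 +
       (P[, 2] - (A[2] + t * d[2]))^2 +
       (P[, 3] - (A[3] + t * d[3]))^2)
}

# grid of physical voxel-center coordinates (um) for an index box (1-based)
coord_grid <- function(zr, yr, xr, voxel_size_um) {
  g <- expand.grid(z = zr, y = yr, x = xr, KEEP.OUT.ATTRS = FALSE)
  cbind((g$z - 1) * voxel_size_um[1],
        (g$y - 1) * voxel_size_um[2],
        (g$x - 1) * voxel_size_um[3])
}

#' 3D connected-component labeling
#'
#' Labels connected foreground components of a binary volume under 6- or
#' 26-connectivity.
#'
#' @param mask logical 3D array in (z, y, x) order.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  check_volume(mask, "mask")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26", call. = FALSE)
  .cc_label_3d(as.logical(mask), dim(mask), as.integer(connectivity))
}

#' Anisotropic Euclidean distance transform
#'
#' For every foreground voxel, the distance (in physical units) to the center
#' of the nearest background voxel, computed with per-axis voxel spacing.
#'
#' @param mask logical 3D array in (z, y, x) order.
#' @param voxel_size_um positive spacing triple (z, y, x).
#' @return numeric array of distances in micrometres; 0 on background.
#' @export
distance_transform <- function(mask, voxel_size_um = c(1, 1, 1)) {
  check_volume(mask, "mask")
  voxel_size_um <- check_triple(voxel_size_um, "voxel_size_um")
  .edt_3d(as.logical(mask), dim(mask), voxel_size_um)
}

#' Homotopic thinning skeleton of a binary volume
#'
#' Curve skeleton obtained by deleting simple boundary voxels in increasing
#' distance-transform order until only a topology- and endpoint-preserving
#' 1-voxel-wide structure remains.
#'
#' @inheritParams distance_transform
#' @return logical 3D array marking skeleton voxels.
#' @export
skeletonize <- function(mask, voxel_size_um = c(1, 1, 1)) {
  check_volume(mask, "mask")
  voxel_size_um <- check_triple(voxel_size_um, "voxel_size_um")
  pri <- .edt_3d(as.logical(mask), dim(mask), voxel_size_um)
  .skeletonize_3d(as.logical(mask), dim(mask), as.numeric(pri), voxel_size_um)
}
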