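# Multilevel chunked volume pyramids. Level 0 is the native stack; each
# coarser level is a block reduction of the previous one. On disk a pyramid
# is a directory store (one subdirectory per level of raw little-endian
# uint16 chunks plus JSON metadata), functionally a minimal zarr-like layout.

# block reduction by integer factors; mean averages the actual members of
# partial edge blocks and rounds half-to-even, max takes the block maximum
block_reduce <- function(arr, factors, method = c("mean", "max")) {
  method <- match.arg(method)
  d <- dim(arr)
  f <- pmax(1L, as.integer(factors))
  od <- as.integer(ceiling(d / f))
  if (method == "mean") {
    n <- length(arr)
    i <- seq_len(n) - 1L
    z <- i %% d[1]; y <- (i %/% d[1]) %% d[2]; x <- i %/% (d[1] * d[2])
    gid <- (z %/% f[1]) + od[1] * ((y %/% f[2]) + od[2] * (x %/% f[3]))
    sums <- rowsum(as.numeric(arr), gid, reorder = TRUE)
    cnts <- rowsum(rep(1, n), gid, reorder = TRUE)
    out <- as_u16(array(sums / cnts, dim = od))
  } else {
    out <- array(-Inf, dim = od)
    idx <- function(k, axis) pmin(seq(1L, d[axis], by = f[axis]) + k, d[axis])
    for (a in 0:(f[1] - 1L)) for (b in 0:(f[2] - 1L)) for (c in 0:(f[3] - 1L)) {
      out <- pmax(out, arr[idx(a, 1L), idx(b, 2L), idx(c, 3L), drop = FALSE])
    }
    out <- as_u16(out)
  }
  out
}

#' Build a multilevel chunked volume pyramid from stitched sections
#'
#' Stacks section images into a level-0 volume at the acquisition voxel size
#' and derives coarser levels by per-axis block reduction until the coarsest
#' level fits within `max_coarse_vox` voxels per axis. Mean reduction rounds
#' half-to-even to 16-bit integers; reading back the full extent of level 0
#' reproduces the input sections bit-exactly.
#'
#' @param sections ordered list of `section_image` objects (one per z, same
#'   shape and channel), or a (z, y, x) integer array.
#' @param voxel_size_um level-0 voxel size (z, y, x) in micrometres; when
#'   sections carry `pixel_size_um`, only the z (section thickness) component
#'   need be meaningful.
#' @param chunk_shape_vox chunk shape (z, y, x) used by the directory store.
#' @param factors per-level reduction factor triple, recycled across levels.
#' @param method block reduction method, `"mean"` or `"max"`.
#' @param max_coarse_vox stop adding levels once every axis of the coarsest
#'   level is at most this many voxels.
#' @param channel channel label stored in the metadata.
#' @return a `volume_pyramid`: list of levels (each with `data`,
#'   `voxel_size_um`, `shape`, `chunk_shape`), plus `channel`, `method`,
#'   `factors` and `meta`.
#' @export
build_pyramid <- function(sections, voxel_size_um = c(1, 0.32, 0.32),
                          chunk_shape_vox = c(64L, 64L, 64L),
                          factors = c(2L, 2L, 2L),
                          method = c("mean", "max"),
                          max_coarse_vox = 256L,
                          channel = NULL) {
  method <- match.arg(method)
  if (is.array(sections) && length(dim(sections)) == 3L) {
    vol <- sections
  } else {
    if (!length(sections)) stop("no sections supplied", call. = FALSE)
    shp <- dim(sections[[1L]]$pixels)
    for (i in seq_along(sections)) {
      if (!identical(dim(sections[[i]]$pixels), shp))
        stop(sprintf("section at z index %d has inconsistent shape", i), call. = FALSE)
    }
    zi <- vapply(sections, function(s) as.integer(s$section_index), integer(1))
    if (any(diff(zi) <= 0)) stop("sections must be in strictly increasing z order",
                                 call. = FALSE)
    channel <- channel %||% sections[[1L]]$channel
    ps <- sections[[1L]]$pixel_size_um
    if (!anyNA(ps)) voxel_size_um <- c(voxel_size_um[1], ps)
    vol <- array(0L, dim = c(length(sections), shp))
    for (i in seq_along(sections)) vol[i, , ] <- sections[[i]]$pixels
  }
  voxel_size_um <- check_triple(voxel_size_um, "voxel_size_um")
  vol <- as_u16(vol)

  levels <- list(list(data = vol, voxel_size_um = voxel_size_um,
                      shape = dim(vol),
                      chunk_shape = pmin(as.integer(chunk_shape_vox), dim(vol))))
  f <- pmax(1L, as.integer(factors))
  while (any(levels[[length(levels)]]$shape > max_coarse_vox) &&
         all(levels[[length(levels)]]$shape > 1L)) {
    prev <- levels[[length(levels)]]
    red <- block_reduce(prev$data, f, method)
    levels[[length(levels) + 1L]] <- list(
      data = red,
      voxel_size_um = prev$voxel_size_um * f,
      shape = dim(red),
      chunk_shape = pmin(as.integer(chunk_shape_vox), dim(red)))
  }
  structure(list(levels = levels, channel = channel %||% "unknown",
                 method = method, factors = f, dtype = "uint16",
                 meta = list(created = "heartvox", reduction = method),
                 path = NULL),
            class = "volume_pyramid")
}

#' @method print volume_pyramid
#' @export
print.volume_pyramid <- function(x, ...) {
  cat("<volume_pyramid>", length(x$levels), "levels,", x$channel, "channel,",
      x$method, "reduction\n")
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: %s vox at %s um%s\n", i - 1L,
                paste(l$shape, collapse = " x "),
                paste(signif(l$voxel_size_um, 4), collapse = " x "),
                if (is.null(l$data)) " [on disk]" else ""))
  }
  invisible(x)
}

chunk_file <- function(ci) sprintf("c_%d_%d_%d.bin", ci[1], ci[2], ci[3])

#' Write a pyramid to a chunked directory store
#'
#' One subdirectory per level containing raw little-endian uint16 chunk files
#' `c_<zi>_<yi>_<xi>.bin` (chunk indices 0-based, edge chunks truncated) and a
#' `level.json` with shape, voxel size, chunk shape and dtype; top-level
#' `pyramid.json` records channel, levels and reduction method.
#'
#' @param pyr a [volume_pyramid][build_pyramid].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_pyramid <- function(pyr, path) {
  stopifnot(inherits(pyr, "volume_pyramid"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (li in seq_along(pyr$levels)) {
    l <- pyr$levels[[li]]
    ldir <- file.path(path, sprintf("level_%d", li - 1L))
    dir.create(ldir, showWarnings = FALSE)
    cs <- l$chunk_shape
    nch <- ceiling(l$shape / cs)
    for (cx in 0:(nch[3] - 1L)) for (cy in 0:(nch[2] - 1L)) for (cz in 0:(nch[1] - 1L)) {
      zr <- (cz * cs[1] + 1L):min((cz + 1L) * cs[1], l$shape[1])
      yr <- (cy * cs[2] + 1L):min((cy + 1L) * cs[2], l$shape[2])
      xr <- (cx * cs[3] + 1L):min((cx + 1L) * cs[3], l$shape[3])
      blk <- l$data[zr, yr, xr, drop = FALSE]
      con <- file(file.path(ldir, chunk_file(c(cz, cy, cx))), "wb")
      writeBin(as.integer(blk), con, size = 2L, endian = "little")
      close(con)
    }
    jsonlite::write_json(list(shape = l$shape, voxel_size_um = l$voxel_size_um,
                              chunk_shape = cs, dtype = "uint16"),
                         file.path(ldir, "level.json"), auto_unbox = FALSE)
  }
  jsonlite::write_json(list(channel = pyr$channel, n_levels = length(pyr$levels),
                            method = pyr$method, factors = pyr$factors,
                            meta = pyr$meta),
                       file.path(path, "pyramid.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Open a pyramid directory store
#'
#' Loads metadata only; voxel data stays on disk and is fetched per chunk by
#' [read_region()].
#'
#' @param path directory written by [write_pyramid()].
#' @return a disk-backed `volume_pyramid` (level `data` fields are `NULL`).
#' @export
open_pyramid <- function(path) {
  top <- jsonlite::read_json(file.path(path, "pyramid.json"), simplifyVector = TRUE)
  levels <- lapply(seq_len(top$n_levels), function(li) {
    m <- jsonlite::read_json(file.path(path, sprintf("level_%d", li - 1L), "level.json"),
                             simplifyVector = TRUE)
    list(data = NULL, voxel_size_um = m$voxel_size_um,
         shape = as.integer(m$shape), chunk_shape = as.integer(m$chunk_shape))
  })
  structure(list(levels = levels, channel = top$channel, method = top$method,
                 factors = as.integer(top$factors), dtype = "uint16",
                 meta = top$meta, path = path),
            class = "volume_pyramid")
}

#' Read a rectangular region of one pyramid level
#'
#' For in-memory pyramids this slices the level array; for disk-backed
#' pyramids only the chunks intersecting the region are read, so the result
#' is independent of the chunk shape used by the store.
#'
#' @param pyr a [volume_pyramid][build_pyramid] (in memory or opened with
#'   [open_pyramid()]).
#' @param level level index, 0-based (0 = native resolution).
#' @param origin_vox region origin (z, y, x), 0-based voxel indices.
#' @param shape_vox region shape (z, y, x) in voxels; zero-size regions
#'   return an empty array.
#' @return integer (z, y, x) array of the stored voxels.
#' @export
read_region <- function(pyr, level, origin_vox, shape_vox) {
  stopifnot(inherits(pyr, "volume_pyramid"))
  if (level < 0L || level >= length(pyr$levels))
    stop("level out of range", call. = FALSE)
  l <- pyr$levels[[level + 1L]]
  o <- as.integer(origin_vox); s <- as.integer(shape_vox)
  if (any(s < 0L)) stop("shape_vox must be nonnegative", call. = FALSE)
  if (any(s == 0L)) return(array(integer(0), dim = s))
  if (any(o < 0L) || any(o + s > l$shape)) {
    clip <- pmin(pmax(o, 0L), l$shape - 1L)
    stop(sprintf(
      "region out of bounds for level %d (shape %s); nearest valid origin: %s",
      level, paste(l$shape, collapse = "x"), paste(clip, collapse = ",")),
      call. = FALSE)
  }
  zr <- (o[1] + 1L):(o[1] + s[1]); yr <- (o[2] + 1L):(o[2] + s[2])
  xr <- (o[3] + 1L):(o[3] + s[3])
  if (!is.null(l$data)) return(l$data[zr, yr, xr, drop = FALSE])

  cs <- l$chunk_shape
  out <- array(0L, dim = s)
  c0 <- o %/% cs
  c1 <- (o + s - 1L) %/% cs
  ldir <- file.path(pyr$path, sprintf("level_%d", level))
  for (cx in c0[3]:c1[3]) for (cy in c0[2]:c1[2]) for (cz in c0[1]:c1[1]) {
    czr <- (cz * cs[1] + 1L):min((cz + 1L) * cs[1], l$shape[1])
    cyr <- (cy * cs[2] + 1L):min((cy + 1L) * cs[2], l$shape[2])
    cxr <- (cx * cs[3] + 1L):min((cx + 1L) * cs[3], l$shape[3])
    f <- file.path(ldir, chunk_file(c(cz, cy, cx)))
    con <- file(f, "rb")
    blk <- readBin(con, "integer", n = length(czr) * length(cyr) * length(cxr),
                   size = 2L, signed = FALSE, endian = "little")
    close(con)
    dim(blk) <- c(length(czr), length(cyr), length(cxr))
    iz <- intersect(czr, zr); iy <- intersect(cyr, yr); ix <- intersect(cxr, xr)
    out[iz - o[1], iy - o[2], ix - o[3]] <-
      blk[iz - czr[1] + 1L, iy - cyr[1] + 1L, ix - cxr[1] + 1L]
  }
  out
}

#' Resample a pyramid to an arbitrary target voxel size
#'
#' Selects the finest pyramid level needed (the coarsest level whose voxel
#' size does not exceed the target on any axis) and interpolates trilinearly
#' onto the target grid; this handles non-integer ratios such as resampling
#' 0.32-um in-plane data to a 10-um display grid (ratio 31.25). Output voxel
#' (i, j, k) (0-based) is sampled at physical position (i, j, k) * target.
#'
#' @param pyr a [volume_pyramid][build_pyramid] (in-memory).
#' @param target_voxel_um target voxel size (z, y, x), micrometres; must be at
#'   least the level-0 voxel size on every axis (no upsampling).
#' @return integer (z, y, x) array of shape `ceiling(extent / target)` with a
#'   `voxel_size_um` attribute equal to the target.
#' @export
resample_to_voxel <- function(pyr, target_voxel_um) {
  stopifnot(inherits(pyr, "volume_pyramid"))
  target <- check_triple(target_voxel_um, "target_voxel_um")
  v0 <- pyr$levels[[1L]]$voxel_size_um
  if (any(target < v0 - 1e-9))
    stop("target voxel finer than level 0; upsampling is not supported",
         call. = FALSE)
  sel <- 1L
  for (li in seq_along(pyr$levels)) {
    if (all(pyr$levels[[li]]$voxel_size_um <= target + 1e-9)) sel <- li
  }
  l <- pyr$levels[[sel]]
  data <- l$data %||% read_region(pyr, sel - 1L, c(0L, 0L, 0L), l$shape)

  extent <- pyr$levels[[1L]]$shape * v0
  od <- as.integer(ceiling(extent / target))
  pz <- ((0:(od[1] - 1)) * target[1]) / l$voxel_size_um[1]
  py <- ((0:(od[2] - 1)) * target[2]) / l$voxel_size_um[2]
  px <- ((0:(od[3] - 1)) * target[3]) / l$voxel_size_um[3]
  g <- expand.grid(z = pz, y = py, x = px, KEEP.OUT.ATTRS = FALSE)
  vals <- trilinear_sample(data, g$z, g$y, g$x)
  out <- as_u16(array(vals, dim = od))
  attr(out, "voxel_size_um") <- target
  attr(out, "source_level") <- sel - 1L
  out
}

#' Per-level summary of a pyramid
#'
#' @param x a [volume_pyramid][build_pyramid].
#' @param ... unused.
#' @return tibble with one row per level: level, shape, voxel size, chunk
#'   shape, global mean and max (in-memory pyramids only).
#' @export
tidy.volume_pyramid <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$levels), function(li) {
    l <- x$levels[[li]]
    tibble::tibble(level = li - 1L,
                   nz = l$shape[1], ny = l$shape[2], nx = l$shape[3],
                   voxel_z_um = l$voxel_size_um[1],
                   voxel_y_um = l$voxel_size_um[2],
                   voxel_x_um = l$voxel_size_um[3],
                   mean = if (is.null(l$data)) NA_real_ else mean(l$data),
                   max = if (is.null(l$data)) NA_real_ else max(l$data))
  }))
}
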