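# Display products: thickness-limited maximum-intensity projections,
# fuchsia/green two-channel merges, and depth-coded projections in which
# color encodes the slice of origin of each foreground pixel.

axis_index <- function(axis = c("axial", "sagittal", "coronal")) {
  # axial: project along z (native sections); sagittal: along x;
  # coronal: along y. Recorded in output metadata.
  switch(match.arg(axis), axial = 1L, coronal = 2L, sagittal = 3L)
}

#' Maximum-intensity projection over a slab
#'
#' Per-pixel maximum over `thickness_slices` consecutive slices along the
#' chosen anatomical axis. A thickness of one slice reproduces a single
#' section (the convention for displaying the myocardium at 1-um thickness);
#' vascular connectivity is typically shown with slabs hundreds of slices
#' thick.
#'
#' @param volume integer (z, y, x) array.
#' @param axis `"axial"` (along z), `"coronal"` (along y) or `"sagittal"`
#'   (along x).
#' @param start_index first slice of the slab (1-based).
#' @param thickness_slices number of slices in the slab (>= 1).
#' @return 2D matrix of class `heartvox_projection` with attributes `axis`,
#'   `start_index`, `thickness_slices`.
#' @export
max_projection <- function(volume, axis = "axial", start_index = 1L,
                           thickness_slices = dim(volume)[axis_index(axis)]) {
  check_volume(volume)
  ai <- axis_index(axis)
  n <- dim(volume)[ai]
  s0 <- as.integer(start_index)
  th <- as.integer(thickness_slices)
  if (th < 1L || s0 < 1L || s0 + th - 1L > n)
    stop("empty or out-of-range slab", call. = FALSE)
  sl <- function(i) {
    m <- switch(ai, volume[i, , ], volume[, i, ], volume[, , i])
    dim(m) <- dim(volume)[-ai]
    m
  }
  out <- sl(s0)
  if (th > 1L) for (i in (s0 + 1L):(s0 + th - 1L)) out <- pmax(out, sl(i))
  structure(out, class = c("heartvox_projection", class(out)),
            axis = axis, start_index = s0, thickness_slices = th)
}

#' Merge two channel images into a pseudocolor RGB rendering
#'
#' Each channel is contrast-windowed to \[0, 1\] and multiplied by its display
#' color; the per-pixel sum is clipped to the 8-bit range. Defaults follow the
#' fuchsia (myocardium) / green (vasculature) convention; where both channels
#' saturate the result whitens, since fuchsia + green covers all three
#' primaries.
#'
#' @param myo,vasc 2D intensity matrices of equal shape.
#' @param myo_color,vasc_color RGB triples in 0..255.
#' @param myo_window,vasc_window contrast windows `c(lo, hi)`; default the
#'   image range.
#' @return integer array (rows, cols, 3) in 0..255, class `heartvox_rgb`.
#' @export
merge_channels <- function(myo, vasc,
                           myo_color = c(255, 0, 255),
                           vasc_color = c(0, 255, 0),
                           myo_window = NULL, vasc_window = NULL) {
  if (!identical(dim(myo), dim(vasc)))
    stop("channel shapes differ", call. = FALSE)
  win <- function(x, w) {
    w <- w %||% range(as.numeric(x))
    if (w[2] <= w[1]) return(array(0, dim(x)))
    pmin(pmax((as.numeric(x) - w[1]) / (w[2] - w[1]), 0), 1)
  }
  m <- win(myo, myo_window)
  v <- win(vasc, vasc_window)
  out <- array(0L, dim = c(dim(myo), 3L))
  for (k in 1:3) {
    ch <- pmin(round(m * myo_color[k] + v * vasc_color[k]), 255)
    out[, , k] <- as.integer(ch)
  }
  structure(out, class = "heartvox_rgb")
}

#' Linearized depth colormap
#'
#' `k` colors sampled at equal intervals along a perceptually ordered HSV hue
#' sweep from blue (240 degrees, shallow) to red (0 degrees, deep).
#'
#' @param k number of slices.
#' @param hue_range hue sweep endpoints in degrees.
#' @return integer k x 3 matrix of RGB values in 0..255.
#' @export
depth_colormap <- function(k, hue_range = c(240, 0)) {
  hues <- if (k == 1L) hue_range[1] else
    seq(hue_range[1], hue_range[2], length.out = k)
  cols <- grDevices::col2rgb(hsv(hues / 360, 1, 1))
  t(cols)[, 1:3, drop = FALSE]
}

#' Depth-coded projection of an image stack
#'
#' Implements sequential depth coding of a stack: every image is binarized at
#' the threshold; the color bar is linearized over the number of images, each
#' image is assigned the corresponding single color, and the colored images
#' are stacked in order. Where a pixel is foreground in several slices, the
#' later slice wins under `order = "last_hit"` (sequential stacking) or the
#' first under `"first_hit"`.
#'
#' @param stack (z, y, x) array or list of k equal-shape 2D images, ordered by
#'   depth.
#' @param threshold binarization threshold, or `"auto"` for a global Otsu
#'   threshold over the whole slab histogram.
#' @param order `"last_hit"` or `"first_hit"`.
#' @param colormap k x 3 RGB matrix (0..255), or a function of k; default
#'   [depth_colormap()].
#' @return a `depth_coded` object: list with `rgb` (rows x cols x 3, 0..255),
#'   `colormap`, `slice_of_origin` (integer matrix of winning 1-based slice
#'   indices, `NA` on background) and `threshold_used`.
#' @export
depth_code <- function(stack, threshold = "auto",
                       order = c("last_hit", "first_hit"),
                       colormap = depth_colormap) {
  order <- match.arg(order)
  if (is.list(stack)) {
    k <- length(stack)
    if (k == 0L) stop("empty stack", call. = FALSE)
    arr <- array(0, dim = c(k, dim(stack[[1L]])))
    for (i in seq_len(k)) arr[i, , ] <- stack[[i]]
    stack <- arr
  }
  check_volume(stack, "stack")
  k <- dim(stack)[1]
  thr <- if (identical(threshold, "auto")) otsu_threshold(stack) else threshold
  if (thr > max(stack) || thr < min(stack))
    warning("threshold outside the data range; result is all background")

  cmap <- if (is.function(colormap)) colormap(k) else colormap
  stopifnot(nrow(cmap) == k, ncol(cmap) == 3)

  origin <- matrix(NA_integer_, dim(stack)[2], dim(stack)[3])
  idx_seq <- if (order == "last_hit") seq_len(k) else rev(seq_len(k))
  for (i in idx_seq) {
    fg <- matrix(stack[i, , ] >= thr, dim(stack)[2], dim(stack)[3])
    origin[fg] <- i            # later assignments overwrite earlier ones
  }
  rgbimg <- array(0L, dim = c(dim(origin), 3L))
  fg <- !is.na(origin)
  for (ch in 1:3) {
    plane <- matrix(0L, nrow(origin), ncol(origin))
    plane[fg] <- as.integer(cmap[origin[fg], ch])
    rgbimg[, , ch] <- plane
  }
  structure(list(rgb = structure(rgbimg, class = "heartvox_rgb"),
                 colormap = cmap,
                 slice_of_origin = origin,
                 threshold_used = thr,
                 order = order),
            class = "depth_coded")
}

#' @method print depth_coded
#' @export
print.depth_coded <- function(x, ...) {
  cat("<depth_coded>", nrow(x$slice_of_origin), "x", ncol(x$slice_of_origin),
      "px,", nrow(x$colormap), "slices,", x$order,
      sprintf("(threshold %.4g)\n", x$threshold_used))
  invisible(x)
}

raster_from_rgb <- function(rgbimg) {
  grDevices::rgb(rgbimg[, , 1] / 255, rgbimg[, , 2] / 255, rgbimg[, , 3] / 255)
}

gg_raster <- function(r, nr, nc, title = NULL) {
  dim(r) <- c(nr, nc)
  df <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  df$fill <- as.vector(r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
#' @export
autoplot.depth_coded <- function(object, ...) {
  gg_raster(raster_from_rgb(object$rgb), nrow(object$slice_of_origin),
            ncol(object$slice_of_origin), "depth-coded projection")
}

#' @export
autoplot.heartvox_rgb <- function(object, ...) {
  gg_raster(raster_from_rgb(object), dim(object)[1], dim(object)[2], NULL)
}

#' @export
autoplot.heartvox_projection <- function(object, ...) {
  v <- as.numeric(object)
  rng <- range(v)
  g <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  gg_raster(grDevices::gray(g), nrow(object), ncol(object),
            sprintf("%s MIP (%d slices)", attr(object, "axis"),
                    attr(object, "thickness_slices")))
}

#' @export
plot.depth_coded <- function(x, ...) print(autoplot(x, ...))
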