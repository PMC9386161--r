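#' Scale calibration for morphometry
#'
#' Defines the physical size of a pixel/voxel so measurements are reported in
#' micrometres, mirroring the set-scale step of interactive measurement
#' tools.
#'
#' @param pixel_size_um in-plane pixel size, a positive pair (row, col) in
#'   micrometres (a scalar is recycled).
#' @param section_thickness_um section (z) thickness in micrometres.
#' @return a `scale_calibration` object.
#' @export
scale_calibration <- function(pixel_size_um = c(0.32, 0.32),
                              section_thickness_um = 1) {
  pixel_size_um <- rep_len(as.numeric(pixel_size_um), 2L)
  if (any(pixel_size_um <= 0) || section_thickness_um <= 0)
    stop("calibration values must be positive", call. = FALSE)
  structure(list(pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um),
            class = "scale_calibration")
}

voxel_size_of <- function(cal) c(cal$section_thickness_um, cal$pixel_size_um)

#' Calibrated point-to-point distance in an image
#'
#' Euclidean distance between two pixel positions with anisotropic pixel
#' scaling: displacement components are multiplied element-wise by the
#' calibrated pixel sizes.
#'
#' @param p_start,p_end pixel positions `(row, col)`.
#' @param cal a [scale_calibration()].
#' @return distance in micrometres.
#' @export
measure_distance <- function(p_start, p_end, cal = scale_calibration()) {
  d <- (as.numeric(p_end) - as.numeric(p_start)) * cal$pixel_size_um
  out <- sqrt(sum(d^2))
  if (out == 0) warning("start and end points are identical; distance 0")
  out
}

#' Fit an ellipse to a 2D nucleus mask by second moments
#'
#' Normalized second central moments (with the 1/12 pixel-integration term,
#' the convention of ImageJ's Fit Ellipse) computed in calibrated
#' micrometre coordinates; the returned ellipse has the same normalized
#' second moments as the region. Axes are full lengths, major >= minor.
#'
#' @param mask2d logical (row, col) matrix marking the region (>= 5 pixels).
#' @param cal a [scale_calibration()].
#' @return one-row tibble: `major_um`, `minor_um`, `orientation_deg` (angle
#'   of the major axis from the column (x) axis, counter-clockwise, in
#'   (-90, 90]), `area_um2`, `n_px`.
#' @export
fit_nucleus_ellipse <- function(mask2d, cal = scale_calibration()) {
  px <- which(mask2d, arr.ind = TRUE)
  if (nrow(px) < 5L)
    stop("region smaller than 5 pixels: ellipse fit unreliable", call. = FALSE)
  py <- cal$pixel_size_um[1]
  pxs <- cal$pixel_size_um[2]
  yy <- px[, 1] * py
  xx <- px[, 2] * pxs
  mx <- mean(xx); my <- mean(yy)
  # central second moments + pixel-extent correction
  uxx <- mean((xx - mx)^2) + pxs^2 / 12
  uyy <- mean((yy - my)^2) + py^2 / 12
  uxy <- mean((xx - mx) * (yy - my))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  theta <- 0.5 * atan2(2 * uxy, uxx - uyy) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  tibble::tibble(major_um = major, minor_um = minor,
                 orientation_deg = theta,
                 area_um2 = nrow(px) * py * pxs,
                 n_px = nrow(px))
}

#' Nucleus volumes from a labeled 3D volume
#'
#' Volume of each label is its voxel count times the calibrated voxel volume.
#' The cohort summary is the unweighted mean and the sample (n - 1) standard
#' deviation across labels.
#'
#' @param label3d integer (z, y, x) array; 0 = background, labels > 0.
#' @param cal a [scale_calibration()].
#' @return tibble with one row per label (`label`, `n_vox`, `volume_um3`) and
#'   a `cohort` attribute (one-row tibble: `n`, `mean_um3`, `sd_um3`).
#' @export
nucleus_volume <- function(label3d, cal = scale_calibration()) {
  check_volume(label3d, "label3d")
  labs <- sort(unique(label3d[label3d > 0L]))
  if (!length(labs)) stop("no labels in the volume", call. = FALSE)
  voxvol <- prod(voxel_size_of(cal))
  counts <- tabulate(label3d[label3d > 0L], nbins = max(labs))[labs]
  if (any(counts == 0L)) {
    warning("empty labels skipped")
    labs <- labs[counts > 0L]
    counts <- counts[counts > 0L]
  }
  tb <- tibble::tibble(label = as.integer(labs),
                       n_vox = as.integer(counts),
                       volume_um3 = counts * voxvol)
  attr(tb, "cohort") <- tibble::tibble(
    n = nrow(tb),
    mean_um3 = mean(tb$volume_um3),
    sd_um3 = if (nrow(tb) > 1L) sd(tb$volume_um3) else 0)
  tb
}

#' Local vessel diameter at a point
#'
#' The diameter at the skeleton (centerline) voxel nearest the query point:
#' twice the anisotropically weighted distance-transform radius there, with a
#' half-voxel correction for the distance from the last foreground voxel
#' center to the wall.
#'
#' @param mask a [vessel_mask][segment_threshold] or logical volume.
#' @param point_on_vessel query voxel (z, y, x), 1-based; must be foreground.
#' @param voxel_size_um voxel size when `mask` is a bare array.
#' @return one-row tibble: `diameter_um`, the centerline voxel used
#'   (`center_z`, `center_y`, `center_x`) and a `method` note.
#' @export
vessel_diameter <- function(mask, point_on_vessel, voxel_size_um = NULL) {
  vs <- voxel_size_um %||%
    (if (inherits(mask, "vessel_mask")) mask$voxel_size_um else c(1, 1, 1))
  m <- as_mask_array(mask)
  check_volume(m, "mask")
  d <- dim(m)
  p <- as.integer(point_on_vessel)
  if (any(p < 1L) || any(p > d) || !m[p[1], p[2], p[3]])
    stop("point is outside the vessel mask foreground", call. = FALSE)

  # restrict to the component containing the point (bounding box + margin)
  lab <- .cc_label_3d(m, d, 26L)
  comp <- lab == lab[p[1], p[2], p[3]]
  dim(comp) <- d
  idx <- which(comp)
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  zr <- max(1L, min(z) - 2L):min(d[1], max(z) + 2L)
  yr <- max(1L, min(y) - 2L):min(d[2], max(y) + 2L)
  xr <- max(1L, min(x) - 2L):min(d[3], max(x) + 2L)
  sub <- comp[zr, yr, xr, drop = FALSE]

  edt <- .edt_3d(sub, dim(sub), vs)
  skel <- .skeletonize_3d(sub, dim(sub), as.numeric(edt), vs)
  sidx <- which(skel)
  if (!length(sidx)) sidx <- which.max(edt)
  sz <- (sidx - 1L) %% dim(sub)[1]
  sy <- ((sidx - 1L) %/% dim(sub)[1]) %% dim(sub)[2]
  sx <- (sidx - 1L) %/% (dim(sub)[1] * dim(sub)[2])
  p_local <- p - c(zr[1], yr[1], xr[1])          # 0-based local
  dd <- ((sz - p_local[1]) * vs[1])^2 + ((sy - p_local[2]) * vs[2])^2 +
        ((sx - p_local[3]) * vs[3])^2
  k <- which.min(dd)
  inplane <- min(vs[2], vs[3])
  radius <- max(edt[sidx[k]] - 0.5 * inplane, 0.5 * inplane)
  ctr <- c(sz[k], sy[k], sx[k]) + c(zr[1], yr[1], xr[1])  # back to 1-based global
  tibble::tibble(diameter_um = 2 * radius,
                 center_z = ctr[1], center_y = ctr[2], center_x = ctr[3],
                 method = "2x anisotropic EDT at nearest centerline voxel, half-voxel corrected")
}

#' Assemble morphometry records
#'
#' Normalizes heterogeneous measurements into the long record format used by
#' the measurement log (feature id, type, value, unit, location, method),
#' ready to append to a CSV.
#'
#' @param feature_id identifier string.
#' @param feature_type one of `"distance"`, `"nucleus_major_axis"`,
#'   `"nucleus_minor_axis"`, `"nucleus_volume"`, `"vessel_diameter"`.
#' @param value measurement value (> 0).
#' @param unit `"um"` or `"um3"`, matching the feature type.
#' @param location optional voxel coordinates (z, y, x).
#' @param method free-text method note.
#' @return one-row tibble.
#' @export
morphometry_record <- function(feature_id, feature_type, value, unit,
                               location = c(NA, NA, NA), method = "") {
  types <- c("distance", "nucleus_major_axis", "nucleus_minor_axis",
             "nucleus_volume", "vessel_diameter")
  if (!feature_type %in% types)
    stop("unknown feature_type", call. = FALSE)
  if (!is.finite(value) || value <= 0)
    stop("morphometry values must be positive", call. = FALSE)
  vol_type <- feature_type == "nucleus_volume"
  if ((vol_type && unit != "um3") || (!vol_type && unit != "um"))
    stop("unit does not match feature_type", call. = FALSE)
  tibble::tibble(feature_id = feature_id, feature_type = feature_type,
                 value = value, unit = unit,
                 z = location[1], y = location[2], x = location[3],
                 method = method)
}
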