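#' Specification of a synthetic dual-channel heart phantom
#'
#' Describes a desk-scale synthetic volume that mimics the geometry of
#' block-face line-scan acquisitions of a counterstained heart: cylindrical
#' cardiomyocytes packed in a three-layer fiber-orientation field (fibers
#' longitudinal in the subepicardial layer, circumferential in the mid-wall,
#' longitudinal again subendocardially), bright elliptical nuclei centered in
#' the myocytes, dark 1-voxel intercalated-disc gaps transverse to each fiber,
#' and a branching vessel tree rendered as bright endothelial walls (hollow
#' above capillary scale, filled below).
#'
#' All triples are in (z, y, x) order; the default voxel size
#' `c(1, 0.32, 0.32)` micrometres corresponds to 0.32 x 0.32 um in-plane
#' sampling with 1-um sections. Intensities are 16-bit unsigned.
#'
#' @param volume_shape_vox integer triple (z, y, x), voxels.
#' @param voxel_size_um positive real triple (z, y, x), micrometres.
#' @param myocyte_radius_um radius of the cylindrical myocytes.
#' @param nucleus_axes_um full axes (major, minor, minor) of the ellipsoidal
#'   nuclei, micrometres; major axis lies along the local fiber direction.
#' @param disc_spacing_um spacing of intercalated-disc gaps along each fiber.
#' @param layer_boundaries_frac two strictly increasing fractions in (0, 1)
#'   splitting the wall-depth (y) extent into epi / mid / endo layers.
#' @param vessel_tree root branch of a vessel tree built with
#'   [vessel_branch()], or `NULL` for [default_vessel_tree()]; use an empty
#'   `list()` for no vessels.
#' @param capillary_radius_um radius below which branches are rendered as
#'   filled capillaries carrying elongated wall-nucleus streaks.
#' @param background_level,foreground_level flat intensity levels (16-bit).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [emit_strips()]
#' @export
phantom_spec <- function(volume_shape_vox = c(96L, 160L, 160L),
                         voxel_size_um = c(1, 0.32, 0.32),
                         myocyte_radius_um = 6,
                         nucleus_axes_um = c(15.5, 3.5, 3.5),
                         disc_spacing_um = 30,
                         layer_boundaries_frac = c(1 / 3, 2 / 3),
                         vessel_tree = NULL,
                         capillary_radius_um = 1,
                         background_level = 1000,
                         foreground_level = 20000,
                         noise_sd = 0.02 * (foreground_level - background_level),
                         seed = 1L) {
  spec <- structure(list(
    volume_shape_vox = as.integer(volume_shape_vox),
    voxel_size_um = as.numeric(voxel_size_um),
    myocyte_radius_um = myocyte_radius_um,
    nucleus_axes_um = as.numeric(nucleus_axes_um),
    disc_spacing_um = disc_spacing_um,
    layer_boundaries_frac = as.numeric(layer_boundaries_frac),
    vessel_tree = vessel_tree,
    capillary_radius_um = capillary_radius_um,
    background_level = background_level,
    foreground_level = foreground_level,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$volume_shape_vox) != 3 || any(spec$volume_shape_vox <= 0))
    stop("invalid phantom spec: volume_shape_vox must be a positive integer triple",
         call. = FALSE)
  check_triple(spec$voxel_size_um, "voxel_size_um")
  if (spec$myocyte_radius_um <= 0 || spec$capillary_radius_um <= 0)
    stop("invalid phantom spec: radii must be positive", call. = FALSE)
  ax <- spec$nucleus_axes_um
  if (length(ax) != 3 || any(ax <= 0) || ax[1] < ax[2] || ax[1] < ax[3])
    stop("invalid phantom spec: nucleus major axis must be >= minor axes", call. = FALSE)
  if (spec$disc_spacing_um <= 0)
    stop("invalid phantom spec: disc_spacing_um must be positive", call. = FALSE)
  lb <- spec$layer_boundaries_frac
  if (length(lb) != 2 || any(lb <= 0) || any(lb >= 1) || lb[1] >= lb[2])
    stop("invalid phantom spec: layer boundaries must be strictly increasing in (0,1)",
         call. = FALSE)
  if (spec$noise_sd < 0)
    stop("invalid phantom spec: noise_sd must be nonnegative", call. = FALSE)
  invisible(spec)
}

#' @method print phantom_spec
#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat("  volume:", paste(x$volume_shape_vox, collapse = " x "), "vox at",
      paste(x$voxel_size_um, collapse = " x "), "um (z, y, x)\n")
  cat("  myocyte radius:", x$myocyte_radius_um, "um; nucleus axes:",
      paste(x$nucleus_axes_um, collapse = "/"), "um; disc spacing:",
      x$disc_spacing_um, "um\n")
  cat("  intensities:", x$background_level, "->", x$foreground_level,
      "(noise sd ", x$noise_sd, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build one branch of a synthetic vessel tree
#'
#' @param start_um branch start point (z, y, x) in micrometres.
#' @param direction direction triple (z, y, x); normalized internally.
#' @param length_um branch length in micrometres.
#' @param radius_um branch radius in micrometres.
#' @param children list of child branches; a child whose `start_um` is `NULL`
#'   is attached at fraction `attach_frac` along this branch's axis.
#' @param attach_frac attachment position along the parent (used when this
#'   branch is a child with `start_um = NULL`).
#' @return a `vessel_branch` list.
#' @export
vessel_branch <- function(start_um = NULL, direction, length_um, radius_um,
                          children = list(), attach_frac = 1) {
  if (radius_um <= 0 || length_um <= 0)
    stop("vessel_branch: length and radius must be positive", call. = FALSE)
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  structure(list(start_um = if (is.null(start_um)) NULL else as.numeric(start_um),
                 direction = d, length_um = length_um, radius_um = radius_um,
                 children = children, attach_frac = attach_frac),
            class = "vessel_branch")
}

#' Default vessel tree for a phantom volume
#'
#' A coronary-like trunk running along z through the mid-wall with five side
#' branches of decreasing caliber, the thinnest at capillary scale.
#'
#' @param extent_um physical volume extent (z, y, x) in micrometres.
#' @param trunk_radius_um trunk radius (aorta-to-artery scale, down-scaled to
#'   the phantom volume).
#' @param n_side number of side branches along the trunk.
#' @return a `vessel_branch` tree.
#' @export
default_vessel_tree <- function(extent_um, trunk_radius_um = 5, n_side = 5) {
  ez <- extent_um[1]; ey <- extent_um[2]; ex <- extent_um[3]
  side <- vector("list", n_side)
  for (i in seq_len(n_side)) {
    ang <- (i - 1) * 2.4
    dir <- c(0.25, sin(ang), cos(ang))
    r <- max(1, trunk_radius_um * (1 - 0.15 * i) * 0.45)
    len <- min(ey, ex) * 0.35
    # attachments stay in the middle half of the trunk so the trunk overhangs
    # each terminal junction by more than its radius (a shorter stub leaves no
    # skeletal arm and the trunk endpoint would be lost)
    side[[i]] <- vessel_branch(NULL, dir, len, r,
                               attach_frac = 0.25 + 0.5 * i / (n_side + 1))
  }
  vessel_branch(start_um = c(0.1 * ez, 0.5 * ey, 0.5 * ex),
                direction = c(1, 0, 0),
                length_um = 0.8 * ez,
                radius_um = trunk_radius_um,
                children = side)
}

# flatten a vessel tree into a segment table; children with NULL start attach
# on the parent axis at attach_frac
flatten_tree <- function(branch, parent_id = NA_integer_, attach_t = NA_real_,
                         acc = NULL) {
  if (is.null(acc)) acc <- new.env()
  if (is.null(acc$rows)) acc$rows <- list()
  id <- length(acc$rows) + 1L
  start <- branch$start_um
  if (is.null(start)) {
    stopifnot(!is.na(parent_id))
    p <- acc$rows[[parent_id]]
    start <- p$A + branch$attach_frac * (p$B - p$A)
    attach_t <- branch$attach_frac
  }
  B <- start + branch$direction * branch$length_um
  acc$rows[[id]] <- list(id = id, A = start, B = B, radius = branch$radius_um,
                         parent = parent_id, attach_t = attach_t)
  for (ch in branch$children) flatten_tree(ch, parent_id = id, acc = acc)
  acc
}

# centerline graph from flattened segments: parent edges are split at child
# attachment points so node degrees reflect the branching topology
tree_graph <- function(segs) {
  nodes <- list()
  add_node <- function(p) {
    for (i in seq_along(nodes)) {
      if (sqrt(sum((nodes[[i]] - p)^2)) < 1e-6) return(i)
    }
    nodes[[length(nodes) + 1L]] <<- p
    length(nodes)
  }
  edges <- list()
  for (s in segs) {
    ts <- c(0, 1)
    for (o in segs) {
      if (!is.na(o$parent) && o$parent == s$id) ts <- c(ts, o$attach_t)
    }
    ts <- sort(unique(ts))
    pts <- lapply(ts, function(t) s$A + t * (s$B - s$A))
    ids <- vapply(pts, add_node, integer(1))
    for (k in seq_len(length(ids) - 1L)) {
      edges[[length(edges) + 1L]] <- list(from = ids[k], to = ids[k + 1L],
                                          radius = s$radius, branch = s$id)
    }
  }
  nm <- do.call(rbind, lapply(nodes, function(p) p))
  node_tb <- tibble::tibble(node = seq_along(nodes),
                            z_um = nm[, 1], y_um = nm[, 2], x_um = nm[, 3])
  edge_tb <- dplyr::bind_rows(lapply(edges, tibble::as_tibble))
  edge_tb$length_um <- sqrt((node_tb$z_um[edge_tb$to] - node_tb$z_um[edge_tb$from])^2 +
                            (node_tb$y_um[edge_tb$to] - node_tb$y_um[edge_tb$from])^2 +
                            (node_tb$x_um[edge_tb$to] - node_tb$x_um[edge_tb$from])^2)
  deg <- tabulate(c(edge_tb$from, edge_tb$to), nbins = nrow(node_tb))
  list(nodes = node_tb, edges = edge_tb,
       branch_count = max(0L, sum(deg == 1L) - 2L))
}

#' Generate a synthetic dual-channel heart phantom
#'
#' Renders the myocardium channel (counterstain-like: bright myocyte
#' cylinders, brighter nuclei, dark intercalated-disc gaps) and the vascular
#' channel (bright endothelial tube walls plus capillary wall-nucleus
#' streaks) of a [phantom_spec()], together with voxel-exact ground truth for
#' parameter-recovery tests.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `heart_phantom` with elements
#'   \describe{
#'     \item{channel_myo, channel_vasc}{integer 16-bit (z, y, x) volumes with
#'       a `voxel_size_um` attribute.}
#'     \item{truth}{ground truth: `myocyte_label_volume`,
#'       `nucleus_label_volume`, `nucleus_table` (per-label true axes and
#'       voxel-counted volume), `vessel_mask` (filled tubes),
#'       `vessel_graph` (centerline nodes/edges with radii and
#'       `branch_count`), and `spec`.}
#'   }
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$volume_shape_vox
    vs <- spec$voxel_size_um
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    bg <- spec$background_level
    fgl <- spec$foreground_level
    nuc_level <- min(U16_MAX, round(1.5 * fgl))

    myo <- array(bg, dim = d)
    myo_lab <- array(0L, dim = d)
    nuc_lab <- array(0L, dim = d)

    # --- myocardium: three wall-depth layers along y ------------------------
    b1 <- max(1L, floor(ny * spec$layer_boundaries_frac[1]))
    b2 <- max(b1 + 1L, floor(ny * spec$layer_boundaries_frac[2]))
    layers <- list(list(rows = 1:b1, fiber = "z"),
                   list(rows = (b1 + 1):b2, fiber = "x"),
                   list(rows = (b2 + 1):ny, fiber = "z"))

    r <- spec$myocyte_radius_um
    pitch <- 2 * r + 1           # 1-um interstitial gap between myocytes
    disc_w <- spec$disc_spacing_um
    nuc_tab <- list()
    label_base <- 0L
    nuc_next <- 1L

    zc <- (0:(nz - 1)) * vs[1]
    xc <- (0:(nx - 1)) * vs[3]

    for (li in seq_along(layers)) {
      lay <- layers[[li]]
      rows <- lay$rows
      yc <- (rows - 1) * vs[2]
      nyl <- length(rows)

      if (lay$fiber == "z") {           # fiber axis z; transverse (y, x)
        a_c <- zc; av <- vs[1]; na <- nz
        bmat <- matrix(rep(yc, nx), nrow = nyl)            # (y, x) grids
        cmat <- matrix(rep(xc, each = nyl), nrow = nyl)
      } else {                          # fiber axis x; transverse (z, y)
        a_c <- xc; av <- vs[3]; na <- nx
        bmat <- matrix(rep(zc, nyl), nrow = nz)            # (z, y) grids
        cmat <- matrix(rep(yc, each = nz), nrow = nz)
      }

      db <- (bmat %% pitch) - pitch / 2
      dc <- (cmat %% pitch) - pitch / 2
      occ <- (db^2 + dc^2) <= r^2
      cell_b <- floor(bmat / pitch)
      cell_c <- floor(cmat / pitch)
      ncc <- max(cell_c) + 1L
      cell_id <- ifelse(occ, cell_b * ncc + cell_c + 1, 0)

      # disc planes are phase-shifted by half a spacing so the volume does
      # not begin on a disc (an all-dark first section)
      seg <- floor((a_c + disc_w / 2) / disc_w)  # along-fiber segment index
      nseg <- max(seg) + 1L
      disc <- ((a_c + disc_w / 2) %% disc_w) < av

      if (lay$fiber == "z") {
        occ3 <- array(rep(as.vector(occ), each = nz), dim = c(nz, nyl, nx))
        lab3 <- outer(seg, cell_id, function(s, cid)
          ifelse(cid > 0, label_base + (cid - 1) * nseg + s + 1, 0))
        disc3 <- array(rep(disc, times = nyl * nx), dim = c(nz, nyl, nx))
      } else {
        occ3 <- array(rep(as.vector(occ), times = nx), dim = c(nz, nyl, nx))
        lab3 <- array(0, dim = c(nz, nyl, nx))
        for (k in seq_len(nx)) {
          cid <- cell_id
          lab3[, , k] <- ifelse(cid > 0, label_base + (cid - 1) * nseg + seg[k] + 1, 0)
        }
        disc3 <- array(rep(disc, each = nz * nyl), dim = c(nz, nyl, nx))
      }
      lab3[!occ3] <- 0

      sl <- myo[, rows, , drop = FALSE]
      sl[occ3] <- fgl
      sl[occ3 & disc3] <- bg
      myo[, rows, ] <- sl
      ml <- myo_lab[, rows, , drop = FALSE]
      ml[occ3] <- as.integer(lab3[occ3])
      myo_lab[, rows, ] <- ml
      label_base <- label_base + max(cell_id) * nseg

      # nuclei: one per myocyte segment, centered, major axis along the fiber
      ax <- spec$nucleus_axes_um / 2             # semi-axes (major, minor, minor)
      cells_b <- unique(cell_b[occ])
      cells_c <- unique(cell_c[occ])
      for (cb in cells_b) for (cc in cells_c) {
        ctr_b <- cb * pitch + pitch / 2
        ctr_c <- cc * pitch + pitch / 2
        if (ctr_b > max(bmat) || ctr_c > max(cmat)) next
        for (sg in 0:(nseg - 1L)) {
          ctr_a <- sg * disc_w                   # segment center (shifted phase)
          if (ctr_a > (na - 1) * av) next
          # bounding box in (z, y, x) index space
          if (lay$fiber == "z") {
            ctr <- c(ctr_a, ctr_b, ctr_c); semi <- c(ax[1], ax[2], ax[3])
          } else {
            ctr <- c(ctr_b, ctr_c, ctr_a); semi <- c(ax[2], ax[3], ax[1])
          }
          zr <- max(1L, floor((ctr[1] - semi[1]) / vs[1]) + 1L):min(nz, ceiling((ctr[1] + semi[1]) / vs[1]) + 1L)
          yr_g <- max(rows[1], floor((ctr[2] - semi[2]) / vs[2]) + 1L):min(rows[nyl], ceiling((ctr[2] + semi[2]) / vs[2]) + 1L)
          xr <- max(1L, floor((ctr[3] - semi[3]) / vs[3]) + 1L):min(nx, ceiling((ctr[3] + semi[3]) / vs[3]) + 1L)
          if (!length(zr) || !length(yr_g) || !length(xr)) next
          P <- coord_grid(zr, yr_g, xr, vs)
          inside <- ((P[, 1] - ctr[1]) / semi[1])^2 +
                    ((P[, 2] - ctr[2]) / semi[2])^2 +
                    ((P[, 3] - ctr[3]) / semi[3])^2 <= 1
          if (!any(inside)) next
          sub_lab <- myo_lab[zr, yr_g, xr, drop = FALSE]
          keep <- inside & (as.vector(sub_lab) > 0)   # stay inside the myocyte
          if (!any(keep)) next
          sub <- myo[zr, yr_g, xr, drop = FALSE]
          sub[keep] <- nuc_level
          myo[zr, yr_g, xr] <- sub
          nsub <- nuc_lab[zr, yr_g, xr, drop = FALSE]
          nsub[keep] <- nuc_next
          nuc_lab[zr, yr_g, xr] <- nsub
          nuc_tab[[nuc_next]] <- tibble::tibble(
            label = nuc_next,
            major_um = spec$nucleus_axes_um[1],
            minor_um = spec$nucleus_axes_um[2],
            z_um = ctr[1], y_um = ctr[2], x_um = ctr[3],
            n_vox = sum(keep),
            volume_um3 = sum(keep) * prod(vs))
          nuc_next <- nuc_next + 1L
        }
      }
    }

    # --- vasculature --------------------------------------------------------
    vasc <- array(bg, dim = d)
    vessel_mask <- array(FALSE, dim = d)
    extent <- (d - 1) * vs
    tree <- spec$vessel_tree
    if (is.null(tree)) tree <- default_vessel_tree(extent)
    graph <- NULL
    if (inherits(tree, "vessel_branch")) {
      segs <- flatten_tree(tree)$rows
      clipped <- FALSE
      inplane <- min(vs[2], vs[3])
      # wall must comfortably exceed the coarsest voxel pitch (including the
      # sqrt(2) diagonal) or rasterization pinholes open the lumen
      wall_th <- 1.2 * max(vs)
      for (s in segs) {
        if (any(s$A < -1e-9) || any(s$B < -1e-9) ||
            any(s$A > extent + 1e-9) || any(s$B > extent + 1e-9)) clipped <- TRUE
        rmax <- s$radius + 2 * max(vs)
        lo <- pmin(s$A, s$B) - rmax; hi <- pmax(s$A, s$B) + rmax
        zr <- max(1L, floor(lo[1] / vs[1]) + 1L):min(nz, ceiling(hi[1] / vs[1]) + 1L)
        yr <- max(1L, floor(lo[2] / vs[2]) + 1L):min(ny, ceiling(hi[2] / vs[2]) + 1L)
        xr <- max(1L, floor(lo[3] / vs[3]) + 1L):min(nx, ceiling(hi[3] / vs[3]) + 1L)
        if (!length(zr) || !length(yr) || !length(xr)) next
        P <- coord_grid(zr, yr, xr, vs)
        dist <- capsule_distance(P, s$A, s$B)
        tube <- dist <= s$radius
        vm <- vessel_mask[zr, yr, xr, drop = FALSE]
        vm[tube] <- TRUE
        vessel_mask[zr, yr, xr] <- vm
        hollow <- s$radius > 3 * inplane
        lit <- if (hollow) tube & (dist >= s$radius - wall_th) else tube
        sub <- vasc[zr, yr, xr, drop = FALSE]
        sub[lit] <- pmax(sub[lit], fgl)
        vasc[zr, yr, xr] <- sub

        # endothelial nucleus streaks on capillary-scale walls
        if (s$radius <= 1.5 * spec$capillary_radius_um) {
          nstreak <- floor(sqrt(sum((s$B - s$A)^2)) / 15)
          if (nstreak > 0) {
            axis <- (s$B - s$A) / sqrt(sum((s$B - s$A)^2))
            ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
            v <- c(axis[2] * u[3] - axis[3] * u[2],
                   axis[3] * u[1] - axis[1] * u[3],
                   axis[1] * u[2] - axis[2] * u[1])
            for (k in seq_len(nstreak)) {
              tpos <- k / (nstreak + 1)
              ang <- stats::runif(1, 0, 2 * pi)
              ctr <- s$A + tpos * (s$B - s$A) + s$radius * (cos(ang) * u + sin(ang) * v)
              A2 <- ctr - 4 * axis; B2 <- ctr + 4 * axis
              lo2 <- pmin(A2, B2) - 1.5; hi2 <- pmax(A2, B2) + 1.5
              zr2 <- max(1L, floor(lo2[1] / vs[1]) + 1L):min(nz, ceiling(hi2[1] / vs[1]) + 1L)
              yr2 <- max(1L, floor(lo2[2] / vs[2]) + 1L):min(ny, ceiling(hi2[2] / vs[2]) + 1L)
              xr2 <- max(1L, floor(lo2[3] / vs[3]) + 1L):min(nx, ceiling(hi2[3] / vs[3]) + 1L)
              if (!length(zr2) || !length(yr2) || !length(xr2)) next
              P2 <- coord_grid(zr2, yr2, xr2, vs)
              streak <- capsule_distance(P2, A2, B2) <= 0.8
              sub2 <- vasc[zr2, yr2, xr2, drop = FALSE]
              sub2[streak] <- nuc_level
              vasc[zr2, yr2, xr2] <- sub2
            }
          }
        }
      }
      if (clipped) warning("vessel tree branch exits the volume; branch clipped")
      graph <- tree_graph(segs)
    }

    if (spec$noise_sd > 0) {
      myo <- myo + stats::rnorm(length(myo), 0, spec$noise_sd)
      vasc <- vasc + stats::rnorm(length(vasc), 0, spec$noise_sd)
    }
    myo <- as_u16(myo)
    vasc <- as_u16(vasc)
    attr(myo, "voxel_size_um") <- vs
    attr(vasc, "voxel_size_um") <- vs

    structure(list(
      channel_myo = myo,
      channel_vasc = vasc,
      truth = list(
        myocyte_label_volume = myo_lab,
        nucleus_label_volume = nuc_lab,
        nucleus_table = if (length(nuc_tab)) dplyr::bind_rows(nuc_tab)
                        else tibble::tibble(),
        vessel_mask = vessel_mask,
        vessel_graph = graph,
        spec = spec)
    ), class = "heart_phantom")
  })
}

#' @method print heart_phantom
#' @export
print.heart_phantom <- function(x, ...) {
  d <- dim(x$channel_myo)
  cat("<heart_phantom> ", paste(d, collapse = " x "), " vox (z, y, x)\n", sep = "")
  cat("  nuclei:", nrow(x$truth$nucleus_table),
      "; vessel voxels:", sum(x$truth$vessel_mask), "\n")
  if (!is.null(x$truth$vessel_graph))
    cat("  vessel branch count (ground truth):", x$truth$vessel_graph$branch_count, "\n")
  invisible(x)
}

#' Split sections into overlapping line-scan strips
#'
#' Cuts every section (fixed z) of a volume into vertical strips of
#' `strip_width_px` columns, consecutive strips sharing `overlap_px` columns,
#' emulating back-and-forth line-scan acquisition. Alternate strips carry a
#' reversed-scan flag (metadata only; pixel order is already normalized).
#' Optional jitter perturbs the true cut positions to mimic stage drift; the
#' true inter-strip offsets are returned for ground-truth registration tests.
#'
#' @param volume integer (z, y, x) volume, or a single (y, x) section matrix.
#' @param strip_width_px strip width in pixels; must exceed `overlap_px`.
#' @param overlap_px nominal overlap between consecutive strips (>= 0).
#' @param jitter_px maximum column jitter of the true cut positions; row
#'   jitter is capped at 2 px. Jitter draws use the current RNG state.
#' @param channel,pixel_size_um metadata copied onto each strip.
#' @return list with `strips` (list of `strip_image`, ordered by section then
#'   strip) and `true_offsets` (tibble: section, pair, d_row, d_col), the
#'   pairwise offsets between consecutive strips.
#' @export
emit_strips <- function(volume, strip_width_px, overlap_px,
                        jitter_px = 0L, channel = "myocardium",
                        pixel_size_um = c(0.32, 0.32)) {
  if (is.matrix(volume)) volume <- array(volume, dim = c(1L, dim(volume)))
  check_volume(volume)
  if (overlap_px < 0 || strip_width_px <= overlap_px)
    stop("require strip_width_px > overlap_px >= 0", call. = FALSE)
  d <- dim(volume)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  w <- as.integer(strip_width_px); o <- as.integer(overlap_px)
  if (w >= nx) {
    if (w > nx) warning("strip wider than section; emitting a single strip")
    w <- min(w, nx)
    n_strips <- 1L
  } else {
    n_strips <- 1L + ceiling((nx - w) / (w - o))
  }
  jr <- min(as.integer(jitter_px), 2L)
  jc <- as.integer(jitter_px)

  strips <- list()
  offs <- list()
  for (z in seq_len(nz)) {
    starts <- integer(n_strips)
    rowoff <- integer(n_strips)
    for (s in seq_len(n_strips)) {
      nominal <- (s - 1L) * (w - o)
      jitter <- if (jc > 0 && s > 1L) sample(-jc:jc, 1L) else 0L
      starts[s] <- min(max(0L, nominal + jitter), nx - w)
      # vertical stage drift accumulates strip to strip, so consecutive-pair
      # row offsets stay within +/- jr (the registration search window)
      rowoff[s] <- if (jr > 0 && s > 1L) rowoff[s - 1L] + sample(-jr:jr, 1L) else 0L
    }
    if (n_strips > 1L) starts <- cummax(starts)  # keep strips ordered
    margin <- jr * max(1L, n_strips - 1L)
    h <- ny - 2L * margin
    for (s in seq_len(n_strips)) {
      rows <- (1L + margin + rowoff[s]):(ny - margin + rowoff[s])
      px <- volume[z, rows, (starts[s] + 1L):(starts[s] + w)]
      dim(px) <- c(h, w)
      strips[[length(strips) + 1L]] <- structure(list(
        pixels = px, channel = channel, section_index = z,
        strip_index = s, nominal_overlap_px = o,
        pixel_size_um = pixel_size_um,
        scan_reversed = (s %% 2L == 0L)
      ), class = "strip_image")
      if (s > 1L) {
        offs[[length(offs) + 1L]] <- tibble::tibble(
          section = z, pair = s - 1L,
          d_row = rowoff[s] - rowoff[s - 1L],
          d_col = starts[s] - starts[s - 1L])
      }
    }
  }
  list(strips = strips,
       true_offsets = if (length(offs)) dplyr::bind_rows(offs)
                      else tibble::tibble(section = integer(), pair = integer(),
                                          d_row = integer(), d_col = integer()))
}

#' @method print strip_image
#' @export
print.strip_image <- function(x, ...) {
  cat("<strip_image> section", x$section_index, "strip", x$strip_index,
      sprintf("(%d x %d px, overlap %d, %s%s)\n", nrow(x$pixels), ncol(x$pixels),
              x$nominal_overlap_px, x$channel,
              if (x$scan_reversed) ", reversed scan" else ""))
  invisible(x)
}
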