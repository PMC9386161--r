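# Vascular chain: threshold segmentation with lumen filling and small-object
# removal, replayable manual edits, seeded flood-fill tracing with skeleton
# branch counting and per-branch radii from the distance transform.

new_vessel_mask <- function(mask, voxel_size_um, threshold_used,
                            edit_log = list()) {
  structure(list(mask = mask, voxel_size_um = voxel_size_um,
                 threshold_used = threshold_used, edit_log = edit_log),
            class = "vessel_mask")
}

#' @method print vessel_mask
#' @export
print.vessel_mask <- function(x, ...) {
  cat("<vessel_mask>", paste(dim(x$mask), collapse = " x "), "vox,",
      sum(x$mask), "foreground,",
      sprintf("threshold %.4g, %d edits\n", x$threshold_used, length(x$edit_log)))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "vessel_mask")) mask$mask else mask
}

#' Threshold segmentation of the vascular channel
#'
#' Voxels at or above the threshold become foreground. Since large vessels
#' image as hollow endothelial walls, enclosed lumina (background components
#' not connected to the volume border) are filled by default so the mask
#' represents the full vessel. Components smaller than `min_component_vox`
#' are removed.
#'
#' @param volume integer (z, y, x) intensity array.
#' @param threshold numeric threshold, or `"auto"` for a global Otsu
#'   threshold (recorded in `threshold_used`).
#' @param min_component_vox remove connected components smaller than this.
#' @param fill_lumen fill enclosed background cavities (vessel lumina).
#' @param voxel_size_um voxel size (z, y, x) carried on the mask (defaults to
#'   the volume's `voxel_size_um` attribute).
#' @return a `vessel_mask`: binary volume plus `voxel_size_um`,
#'   `threshold_used` and an empty, replayable `edit_log`.
#' @export
segment_threshold <- function(volume, threshold = "auto",
                              min_component_vox = 0L, fill_lumen = TRUE,
                              voxel_size_um = NULL) {
  check_volume(volume)
  if (length(volume) == 0L) stop("empty volume", call. = FALSE)
  voxel_size_um <- voxel_size_um %||% attr(volume, "voxel_size_um") %||% c(1, 1, 1)
  thr <- if (identical(threshold, "auto")) otsu_threshold(volume) else threshold
  mask <- volume >= thr
  dim(mask) <- dim(volume)

  if (fill_lumen && any(mask) && !all(mask)) {
    bg_lab <- .cc_label_3d(!mask, dim(mask), 6L)
    border <- unique(c(bg_lab[c(1L, dim(mask)[1]), , ],
                       bg_lab[, c(1L, dim(mask)[2]), ],
                       bg_lab[, , c(1L, dim(mask)[3])]))
    border <- border[border > 0L]
    enclosed <- bg_lab > 0L & !(bg_lab %in% border)
    mask[enclosed] <- TRUE
  }
  if (min_component_vox > 0L && any(mask)) {
    lab <- .cc_label_3d(mask, dim(mask), 26L)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_component_vox)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  if (all(mask)) warning("segmentation is all foreground")
  if (!any(mask)) warning("segmentation is all background (empty mask)")
  new_vessel_mask(mask, voxel_size_um, thr)
}

#' Apply manual segmentation edits to a mask
#'
#' Edits emulate slice-wise manual correction of an automatic segmentation:
#' each edit adds or removes a labeled 2D region on one section. Edits are
#' applied in order and appended to the mask's edit log, so the final mask can
#' be reproduced by replaying the log on the original automatic mask
#' ([replay_edits()]). Re-applying an identical edit is idempotent.
#'
#' @param mask a [vessel_mask][segment_threshold].
#' @param edits list of edits, each a list with `z` (section index, 1-based),
#'   `op` (`"add"` or `"remove"`) and `region` (logical (y, x) matrix matching
#'   the section shape).
#' @return the edited `vessel_mask` with an extended edit log.
#' @export
apply_manual_edits <- function(mask, edits) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$mask
  for (e in edits) {
    if (e$z < 1L || e$z > dim(m)[1]) stop("edit z out of range", call. = FALSE)
    if (!identical(dim(e$region), dim(m)[2:3]))
      stop("edit region shape does not match the section shape", call. = FALSE)
    sl <- m[e$z, , ]
    if (identical(e$op, "add")) sl[e$region] <- TRUE
    else if (identical(e$op, "remove")) sl[e$region] <- FALSE
    else stop("edit op must be 'add' or 'remove'", call. = FALSE)
    m[e$z, , ] <- sl
  }
  new_vessel_mask(m, mask$voxel_size_um, mask$threshold_used,
                  c(mask$edit_log, edits))
}

#' Replay an edit log on an automatic mask
#'
#' @param mask a [vessel_mask][segment_threshold] (typically the original
#'   automatic segmentation).
#' @param log an edit log from another mask's `edit_log`.
#' @return the mask with the log applied.
#' @export
replay_edits <- function(mask, log) {
  out <- apply_manual_edits(mask, log)
  out$edit_log <- log
  out
}

# skeleton voxel graph: nodes are skeleton voxels, edges 26-adjacency with
# physical edge lengths; returns igraph plus voxel coordinates
skeleton_graph <- function(skel, voxel_size_um) {
  idx <- which(skel)
  if (!length(idx)) return(NULL)
  d <- dim(skel)
  z <- (idx - 1L) %% d[1]
  y <- ((idx - 1L) %/% d[1]) %% d[2]
  x <- (idx - 1L) %/% (d[1] * d[2])
  key <- new.env(hash = TRUE)
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = key)
  ek <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    if (a < 0 || (a == 0 && (b < 0 || (b == 0 && c < 0)))) next  # half-space
    zz <- z + a; yy <- y + b; xx <- x + c
    ok <- zz >= 0 & zz < d[1] & yy >= 0 & yy < d[2] & xx >= 0 & xx < d[3]
    j <- zz + d[1] * (yy + d[2] * xx) + 1L
    ok[ok] <- skel[j[ok]]
    if (!any(ok)) next
    from <- which(ok)
    to <- vapply(as.character(j[ok]), function(k) get(k, envir = key), integer(1))
    w <- sqrt((a * voxel_size_um[1])^2 + (b * voxel_size_um[2])^2 +
              (c * voxel_size_um[3])^2)
    ek[[length(ek) + 1L]] <- cbind(from, to, w)
  }
  if (!length(ek)) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  } else {
    em <- do.call(rbind, ek)
    g <- igraph::graph_from_edgelist(em[, 1:2, drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::E(g)$weight <- em[, 3]
  }
  list(g = g, idx = idx, z = z, y = y, x = x)
}

# prune skeleton spurs: endpoint branches shorter than prune_factor x the
# local radius along the spur are removed, iteratively until stable; vertices
# on the trunk (protected) are never pruned, so short trunk overhangs beyond
# the last junction are not mistaken for spurs
prune_skeleton <- function(sg, radius_at, prune_factor, voxel_size_um,
                           protected = integer(0)) {
  n <- length(sg$idx)
  keep <- rep(TRUE, n)
  if (n == 0L || igraph::ecount(sg$g) == 0L) return(keep)
  coord <- cbind(sg$z * voxel_size_um[1], sg$y * voxel_size_um[2],
                 sg$x * voxel_size_um[3])
  adj <- lapply(igraph::as_adj_list(sg$g), as.integer)
  deg_of <- function(i) sum(keep[adj[[i]]])
  repeat {
    removed <- FALSE
    ends <- which(keep & vapply(seq_len(n), function(i)
      if (keep[i]) deg_of(i) else 2L, integer(1)) == 1L)
    for (e in ends) {
      if (!keep[e] || deg_of(e) != 1L || e %in% protected) next
      path <- e
      cur <- e
      len <- 0
      junc <- NA_integer_
      repeat {
        nb <- adj[[cur]]
        nb <- nb[keep[nb] & !(nb %in% path)]
        if (length(nb) == 0L) break
        nxt <- nb[1L]
        len <- len + sqrt(sum((coord[nxt, ] - coord[cur, ])^2))
        if (deg_of(nxt) > 2L) { junc <- nxt; break }
        path <- c(path, nxt)
        cur <- nxt
      }
      # a spur is judged against its own mean local radius (not the junction
      # radius, which would erase genuine short branches off thick trunks)
      if (!is.na(junc) && len < prune_factor * mean(radius_at[path])) {
        keep[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  keep
}

#' Trace a connected vessel network from a seed point
#'
#' Flood fill from the seed under the chosen connectivity selects one
#' connected vessel component (the paper's workflow: locate the aorta, then
#' follow its branches through consecutive sections). The component is
#' skeletonized by homotopic thinning; spurs shorter than
#' `prune_factor` times the local radius are pruned; the trunk is the longest
#' skeleton path between endpoints and the branch count is the number of
#' remaining degree-1 endpoints excluding the two trunk ends. Per-branch mean
#' radii come from the distance transform along each skeleton branch.
#'
#' @param mask a [vessel_mask][segment_threshold] or logical volume.
#' @param seed_vox seed (z, y, x), 1-based; must be foreground.
#' @param connectivity 6 or 26 (default 26, preserving thin diagonal
#'   capillaries).
#' @param prune_factor spur-pruning factor (multiples of local radius).
#' @param voxel_size_um voxel size when `mask` is a bare array.
#' @return a `branch_report`: list with `branches` (tibble: branch id, voxel
#'   count, length, mean radius, trunk flag), `branch_count`,
#'   `component_voxel_count`, `seed_vox`, `traced_mask` (logical volume) and
#'   `skeleton` (logical volume).
#' @export
trace_from_seed <- function(mask, seed_vox, connectivity = 26L,
                            prune_factor = 3, voxel_size_um = NULL) {
  vs <- voxel_size_um %||%
    (if (inherits(mask, "vessel_mask")) mask$voxel_size_um else c(1, 1, 1))
  m <- as_mask_array(mask)
  check_volume(m, "mask")
  d <- dim(m)
  s <- as.integer(seed_vox)
  if (any(s < 1L) || any(s > d)) stop("seed outside the volume", call. = FALSE)
  if (!m[s[1], s[2], s[3]]) {
    idx <- which(m)
    if (!length(idx)) stop("seed in background and the mask is empty", call. = FALSE)
    z <- (idx - 1L) %% d[1] + 1L
    y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
    x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
    dd <- ((z - s[1]) * vs[1])^2 + ((y - s[2]) * vs[2])^2 + ((x - s[3]) * vs[3])^2
    k <- which.min(dd)
    stop(sprintf("seed (%d,%d,%d) is in background; nearest foreground voxel is (%d,%d,%d)",
                 s[1], s[2], s[3], z[k], y[k], x[k]), call. = FALSE)
  }

  lab <- .cc_label_3d(m, d, as.integer(connectivity))
  traced <- lab == lab[s[1], s[2], s[3]]
  dim(traced) <- d

  edt <- .edt_3d(traced, d, vs)
  skel <- .skeletonize_3d(traced, d, as.numeric(edt), vs)
  sg <- skeleton_graph(skel, vs)
  inplane <- min(vs[2], vs[3])
  radius_at <- pmax(edt[sg$idx] - 0.5 * inplane, 0.5 * inplane)

  # the trunk is the thickest long path (aorta-to-apex), not merely the
  # longest: weight edges by length x local radius so tip-to-tip paths through
  # thin side branches cannot outrank it, then protect it from spur pruning
  trunk_protect <- integer(0)
  if (igraph::ecount(sg$g) > 0L) {
    el <- igraph::as_edgelist(sg$g, names = FALSE)
    wrad <- igraph::E(sg$g)$weight *
      (radius_at[el[, 1]] + radius_at[el[, 2]]) / 2
    trunk_protect <- as.integer(igraph::get_diameter(sg$g, weights = wrad))
  }
  keep <- prune_skeleton(sg, radius_at, prune_factor, vs, trunk_protect)
  g <- igraph::induced_subgraph(sg$g, which(keep))
  kept_idx <- sg$idx[keep]
  kept_rad <- radius_at[keep]

  deg <- igraph::degree(g)
  endpoints <- which(deg == 1L)
  n_end <- length(endpoints)
  branch_count <- max(0L, n_end - 2L)

  # branch decomposition: split the skeleton at junction voxels (degree > 2)
  branches <- tibble::tibble(branch = integer(), n_vox = integer(),
                             length_um = numeric(), mean_radius_um = numeric(),
                             is_trunk = logical())
  if (igraph::vcount(g) > 0L) {
    trunk_v <- integer(0)
    if (n_end >= 2L) {
      el2 <- igraph::as_edgelist(g, names = FALSE)
      wrad2 <- igraph::E(g)$weight * (kept_rad[el2[, 1]] + kept_rad[el2[, 2]]) / 2
      trunk_v <- as.integer(igraph::get_diameter(g, weights = wrad2))
    }
    g_cut <- igraph::delete_vertices(g, which(deg > 2L))
    comp <- igraph::components(g_cut)
    ids <- as.integer(igraph::V(g)[deg <= 2L])
    rows <- lapply(seq_len(comp$no), function(ci) {
      vs_local <- ids[comp$membership == ci]
      if (!length(vs_local)) return(NULL)
      tibble::tibble(branch = ci,
                     n_vox = length(vs_local),
                     length_um = sum_path_length(g, vs_local),
                     mean_radius_um = mean(kept_rad[vs_local]),
                     is_trunk = mean(vs_local %in% trunk_v) > 0.5)
    })
    branches <- dplyr::bind_rows(rows)
    branches <- dplyr::arrange(branches, dplyr::desc(.data$n_vox))
    branches$branch <- seq_len(nrow(branches))
  }

  skel_kept <- array(FALSE, d)
  skel_kept[kept_idx] <- TRUE

  structure(list(branches = branches,
                 branch_count = branch_count,
                 component_voxel_count = sum(traced),
                 seed_vox = s,
                 traced_mask = traced,
                 skeleton = skel_kept,
                 voxel_size_um = vs),
            class = "branch_report")
}

# total weight of edges internal to a vertex subset (approximate branch length)
sum_path_length <- function(g, vids) {
  sub <- igraph::induced_subgraph(g, vids)
  if (igraph::ecount(sub) == 0L) return(0)
  sum(igraph::E(sub)$weight)
}

#' @method print branch_report
#' @export
print.branch_report <- function(x, ...) {
  cat("<branch_report>", x$component_voxel_count, "voxels traced from seed (",
      paste(x$seed_vox, collapse = ","), "); branch count:", x$branch_count, "\n")
  print(x$branches)
  invisible(x)
}

#' @rdname trace_from_seed
#' @param x a `branch_report`.
#' @param ... unused.
#' @export
tidy.branch_report <- function(x, ...) x$branches

#' @rdname trace_from_seed
#' @export
glance.branch_report <- function(x, ...) {
  tibble::tibble(branch_count = x$branch_count,
                 component_voxel_count = x$component_voxel_count,
                 n_branches_tabulated = nrow(x$branches),
                 mean_radius_um = mean(x$branches$mean_radius_um))
}
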