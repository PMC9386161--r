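# One-config end-to-end run: phantom -> strips -> stitching -> pyramids ->
# renders -> vascular chain -> morphometry, with a manifest of output hashes
# so reproducibility is checkable across runs.

#' Default pipeline configuration
#'
#' @return nested list of the configuration consumed by [run_pipeline()];
#'   amend fields or serialize to YAML for the command-line driver.
#' @export
pipeline_config <- function() {
  list(
    phantom = list(volume_shape_vox = c(96L, 128L, 128L),
                   voxel_size_um = c(1, 0.32, 0.32),
                   noise_sd = 380),
    strips = list(strip_width_px = 56L, overlap_px = 20L, jitter_px = 2L),
    stitch = list(policy = "cut", search_radius_px = 10L, row_radius_px = 3L),
    pyramid = list(chunk_shape_vox = c(32L, 32L, 32L), factors = c(2L, 2L, 2L),
                   method = "mean", max_coarse_vox = 64L),
    render = list(depth_slices = 32L, depth_order = "last_hit"),
    vasc = list(min_component_vox = 27L, smoothing_iterations = 10L,
                curvature_kind = "mean")
  )
}

#' Run the whole pipeline from one configuration
#'
#' Generates the phantom, emits and re-stitches strips for both channels,
#' builds and stores the channel pyramids, produces a depth-coded capillary
#' projection and a fuchsia/green merged projection, segments and traces the
#' vasculature, extracts a curvature-colored wall mesh, and measures the
#' nucleus cohort. All outputs are written under `out_dir`; the returned
#' manifest lists each file with its MD5 hash, so two runs with the same
#' config and seed can be checked for byte-identical outputs.
#'
#' @param config configuration list (see [pipeline_config()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir output directory (created).
#' @param seed integer seed driving all randomness.
#' @return tibble manifest: `file`, `md5`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  for (nm in names(base)) {
    config[[nm]] <- utils::modifyList(base[[nm]], config[[nm]] %||% list())
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ph_args <- config$phantom
  ph_args$seed <- seed
  spec <- do.call(phantom_spec, ph_args)
  ph <- generate_phantom(spec)

  # both channels share the acquisition geometry: identical strip jitter
  # (same seed), and offsets estimated once on the structure-dense myocardium
  # channel then reused for the vasculature
  vols <- list(myocardium = ph$channel_myo, vasculature = ph$channel_vasc)
  emitted <- lapply(names(vols), function(ch) {
    with_seed(seed + 1L,
      emit_strips(vols[[ch]], config$strips$strip_width_px,
                  config$strips$overlap_px, config$strips$jitter_px,
                  channel = ch, pixel_size_um = spec$voxel_size_um[2:3]))
  })
  names(emitted) <- names(vols)
  st_myo <- stitch_sections(emitted$myocardium, policy = config$stitch$policy,
                            search_radius_px = config$stitch$search_radius_px,
                            row_radius_px = config$stitch$row_radius_px)
  st_vasc <- stitch_sections(emitted$vasculature, offsets = st_myo$offsets,
                             policy = config$stitch$policy)
  sections <- list(myocardium = st_myo$sections, vasculature = st_vasc$sections)
  utils::write.csv(st_myo$offsets, file.path(out_dir, "offsets.csv"),
                   row.names = FALSE)

  # per-section row jitter shifts each stitched section's origin relative to
  # the (natively aligned) first-strip frame; align sections on that frame and
  # crop to the common extent so the stacked volume has no z-shear
  r0s <- vapply(sections$myocardium, function(s) s$row_origin %||% 0L, integer(1))
  hs <- vapply(sections$myocardium, function(s) nrow(s$pixels), integer(1))
  ws <- vapply(sections$myocardium, function(s) ncol(s$pixels), integer(1))
  common0 <- max(r0s)
  common1 <- min(r0s + hs)
  w <- min(ws)
  for (ch in names(sections)) {
    sections[[ch]] <- mapply(function(s, r0) {
      s$pixels <- s$pixels[(common0 - r0 + 1L):(common1 - r0), 1:w, drop = FALSE]
      s
    }, sections[[ch]], r0s, SIMPLIFY = FALSE)
  }

  for (ch in names(sections)) {
    pyr <- build_pyramid(sections[[ch]],
                         voxel_size_um = spec$voxel_size_um,
                         chunk_shape_vox = config$pyramid$chunk_shape_vox,
                         factors = config$pyramid$factors,
                         method = config$pyramid$method,
                         max_coarse_vox = config$pyramid$max_coarse_vox,
                         channel = ch)
    write_pyramid(pyr, file.path(out_dir, sprintf("pyramid_%s", ch)))
    assign(paste0("pyr_", ch), pyr)
  }
  pyr_myo <- get("pyr_myocardium")
  pyr_vasc <- get("pyr_vasculature")

  # renders: stitched sections may be cropped relative to the raw volume, so
  # all display products come from the stitched level-0 data
  v_m <- pyr_myo$levels[[1L]]$data
  v_v <- pyr_vasc$levels[[1L]]$data
  nzs <- dim(v_v)[1]
  k <- min(config$render$depth_slices, nzs)
  z0 <- max(1L, (nzs - k) %/% 2L)
  dc <- depth_code(v_v[z0:(z0 + k - 1L), , , drop = FALSE],
                   threshold = "auto", order = config$render$depth_order)
  write_rgb_tiff(dc$rgb, file.path(out_dir, "depthcode_vasc.tif"))
  utils::write.csv(data.frame(slice = seq_len(nrow(dc$colormap)),
                              r = dc$colormap[, 1], g = dc$colormap[, 2],
                              b = dc$colormap[, 3]),
                   file.path(out_dir, "depthcode_colormap.csv"),
                   row.names = FALSE)
  soo <- dc$slice_of_origin
  soo[is.na(soo)] <- 0L
  write_tiff16(soo, file.path(out_dir, "depthcode_origin.tif"))

  mip_m <- max_projection(v_m, "axial", 1L, 1L)
  mip_v <- max_projection(v_v, "axial", 1L, dim(v_v)[1])
  merged <- merge_channels(mip_m, mip_v)
  write_rgb_tiff(merged, file.path(out_dir, "merge_fuchsia_green.tif"))

  # vascular chain on the stitched vascular volume
  vm <- segment_threshold(v_v, threshold = "auto",
                          min_component_vox = config$vasc$min_component_vox,
                          voxel_size_um = spec$voxel_size_um)
  if (any(vm$mask)) {
    # seed at the deepest interior voxel (the trunk lumen)
    edt <- .edt_3d(vm$mask, dim(vm$mask), spec$voxel_size_um)
    k <- which.max(edt) - 1L
    dm <- dim(vm$mask)
    seed <- c(k %% dm[1], (k %/% dm[1]) %% dm[2], k %/% (dm[1] * dm[2])) + 1L
    rpt <- trace_from_seed(vm, seed, voxel_size_um = spec$voxel_size_um)
    utils::write.csv(cbind(glance(rpt),
                           tidy(rpt)[which.max(tidy(rpt)$n_vox), c("length_um", "mean_radius_um")]),
                     file.path(out_dir, "branch_report.csv"), row.names = FALSE)
    mesh <- extract_surface(rpt$traced_mask,
                            smoothing_iterations = config$vasc$smoothing_iterations,
                            voxel_size_um = spec$voxel_size_um)
    mesh <- vertex_curvature(mesh, config$vasc$curvature_kind)
    mesh <- colorize_curvature(mesh)
    write_mesh(mesh, file.path(out_dir, "vessel_surface.ply"))
  }

  # morphometry: nucleus cohort from the phantom labels
  nv <- nucleus_volume(ph$truth$nucleus_label_volume,
                       scale_calibration(spec$voxel_size_um[2:3],
                                         spec$voxel_size_um[1]))
  utils::write.csv(nv, file.path(out_dir, "nucleus_volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(nv, "cohort"), file.path(out_dir, "nucleus_cohort.csv"),
                   row.names = FALSE)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  tibble::tibble(file = sub(paste0("^", out_dir, "/?"), "", files),
                 md5 = unname(tools::md5sum(files)))
}
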