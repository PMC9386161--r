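# TIFF and sidecar I/O. Intensity images are 16-bit; the tiff package works
# in [0, 1], so values are scaled by 65535 on write and back on read
# (lossless for integer data).

#' Write a 16-bit intensity image or volume to TIFF
#'
#' Matrices become single-page TIFFs; (z, y, x) volumes become multi-page
#' TIFFs (one page per z).
#'
#' @param img integer matrix or (z, y, x) array, values 0..65535.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(img, path) {
  if (is.array(img) && length(dim(img)) == 3L) {
    pages <- lapply(seq_len(dim(img)[1]), function(z) {
      m <- img[z, , ]
      dim(m) <- dim(img)[2:3]
      m / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a 16-bit TIFF written by [write_tiff16()]
#'
#' @param path TIFF file.
#' @param as_volume return multi-page files as a (z, y, x) array.
#' @return integer matrix or (z, y, x) array.
#' @export
read_tiff16 <- function(path, as_volume = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  to16 <- function(m) {
    out <- as.integer(round(m * 65535))
    dim(out) <- dim(m)
    out
  }
  if (length(pages) == 1L && !as_volume) return(to16(pages[[1L]]))
  if (length(pages) == 1L && as_volume) {
    m <- to16(pages[[1L]])
    if (!is.null(dim(m)) && length(dim(m)) == 2L) return(m)
  }
  vol <- array(0L, dim = c(length(pages), dim(pages[[1L]])))
  for (z in seq_along(pages)) vol[z, , ] <- to16(pages[[z]])
  vol
}

#' Write emitted strips as TIFFs with JSON sidecar metadata
#'
#' One TIFF per strip named `strip_<section>_<strip>.tif` plus a matching
#' `.json` sidecar (channel, section and strip index, nominal overlap, scan
#' direction, pixel size), and `true_offsets.csv` when ground-truth offsets
#' are present.
#'
#' @param emitted result of [emit_strips()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_strips <- function(emitted, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in emitted$strips) {
    stem <- sprintf("strip_%05d_%03d", s$section_index, s$strip_index)
    write_tiff16(s$pixels, file.path(dir, paste0(stem, ".tif")))
    jsonlite::write_json(list(channel = s$channel,
                              section_index = s$section_index,
                              strip_index = s$strip_index,
                              nominal_overlap_px = s$nominal_overlap_px,
                              pixel_size_um = s$pixel_size_um,
                              scan_reversed = s$scan_reversed),
                         file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE)
  }
  if (!is.null(emitted$true_offsets) && nrow(emitted$true_offsets))
    utils::write.csv(emitted$true_offsets, file.path(dir, "true_offsets.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read strips written by [write_strips()]
#'
#' @param dir directory of strip TIFF + JSON sidecar pairs.
#' @return list with `strips` and `true_offsets` (possibly `NULL`), the
#'   format of [emit_strips()].
#' @export
read_strips <- function(dir) {
  metas <- sort(list.files(dir, pattern = "^strip_.*\\.json$", full.names = TRUE))
  strips <- lapply(metas, function(mf) {
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    px <- read_tiff16(sub("\\.json$", ".tif", mf), as_volume = FALSE)
    structure(list(pixels = px, channel = m$channel,
                   section_index = m$section_index,
                   strip_index = m$strip_index,
                   nominal_overlap_px = m$nominal_overlap_px,
                   pixel_size_um = m$pixel_size_um,
                   scan_reversed = m$scan_reversed),
              class = "strip_image")
  })
  offf <- file.path(dir, "true_offsets.csv")
  true_offsets <- if (file.exists(offf))
    tibble::as_tibble(utils::read.csv(offf)) else NULL
  list(strips = strips, true_offsets = true_offsets)
}

#' Write an RGB rendering to TIFF
#'
#' @param rgbimg (rows, cols, 3) array of 0..255 values (`heartvox_rgb`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rgb_tiff <- function(rgbimg, path) {
  arr <- unclass(rgbimg) / 255
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}
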