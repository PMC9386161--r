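#' Estimate the offset between two adjacent line-scan strips
#'
#' Finds the integer translation that maximizes the normalized
#' cross-correlation between the trailing overlap band of the left strip and
#' the leading band of the right strip. The column offset is searched within
#' `search_radius_px` of the nominal offset (strip width minus nominal
#' overlap); the row offset within `row_radius_px` (block-face acquisition has
#' only small vertical drift between strips).
#'
#' @param strip_a,strip_b adjacent [strip_image][emit_strips] objects
#'   (`strip_b$strip_index == strip_a$strip_index + 1`, same section and
#'   channel); plain matrices are accepted with `nominal_overlap_px` taken
#'   from `strip_a` or supplied via `nominal_overlap_px`.
#' @param search_radius_px half-width of the column search window.
#' @param row_radius_px half-width of the row search window.
#' @param nominal_overlap_px override for the nominal overlap when passing
#'   bare matrices.
#' @param min_score correlation below which the estimate is considered
#'   uninformative and the nominal offset is returned with a warning.
#' @return one-row tibble with `d_row`, `d_col` (placement of `strip_b`
#'   relative to `strip_a`: `strip_b` pixel (i, j) aligns with `strip_a` pixel
#'   (i + d_row, j + d_col)), `score` (the maximal correlation, in \[-1, 1\])
#'   and `flagged` (`TRUE` when the overlap band was flat or uninformative and
#'   the nominal offset was returned with score 0).
#' @export
estimate_offset <- function(strip_a, strip_b, search_radius_px = 10L,
                            row_radius_px = 3L, nominal_overlap_px = NULL,
                            min_score = 0.2) {
  a <- if (inherits(strip_a, "strip_image")) strip_a$pixels else strip_a
  b <- if (inherits(strip_b, "strip_image")) strip_b$pixels else strip_b
  if (inherits(strip_a, "strip_image") && inherits(strip_b, "strip_image")) {
    if (strip_b$strip_index != strip_a$strip_index + 1L ||
        strip_b$section_index != strip_a$section_index ||
        !identical(strip_a$channel, strip_b$channel))
      stop("strips must be adjacent (strip_index + 1), same section and channel",
           call. = FALSE)
  }
  o <- nominal_overlap_px %||%
    (if (inherits(strip_a, "strip_image")) strip_a$nominal_overlap_px else
       stop("nominal_overlap_px required for bare matrices", call. = FALSE))
  wa <- ncol(a)
  nominal <- wa - o

  best <- list(score = -Inf, d_row = 0L, d_col = nominal)
  any_valid <- FALSE
  for (dc in (nominal - search_radius_px):(nominal + search_radius_px)) {
    ow <- wa - dc                       # overlap width at this candidate
    if (ow < 1L || dc < 1L || ow > ncol(b)) next
    for (dr in (-row_radius_px):row_radius_px) {
      ra <- max(1L, 1L + dr):min(nrow(a), nrow(b) + dr)
      rb <- ra - dr
      if (length(ra) < 2L) next
      band_a <- as.numeric(a[ra, (dc + 1L):wa])
      band_b <- as.numeric(b[rb, 1:ow])
      if (sd(band_a) == 0 || sd(band_b) == 0) next
      sc <- cor(band_a, band_b)
      any_valid <- TRUE
      if (sc > best$score) best <- list(score = sc, d_row = dr, d_col = dc)
    }
  }
  if (!any_valid) {
    warning("overlap band is flat; returning nominal offset with score 0")
    return(tibble::tibble(d_row = 0L, d_col = as.integer(nominal),
                          score = 0, flagged = TRUE))
  }
  if (best$score < min_score) {
    warning(sprintf(
      "best correlation %.3f below min_score %.2f; returning nominal offset",
      best$score, min_score))
    return(tibble::tibble(d_row = 0L, d_col = as.integer(nominal),
                          score = best$score, flagged = TRUE))
  }
  tibble::tibble(d_row = as.integer(best$d_row), d_col = as.integer(best$d_col),
                 score = best$score, flagged = FALSE)
}

#' Estimate offsets for every adjacent strip pair of one section
#'
#' @param strips list of [strip_image][emit_strips] objects of one section,
#'   ordered by strip index.
#' @inheritParams estimate_offset
#' @return tibble with one row per pair: `pair`, `d_row`, `d_col`, `score`,
#'   `flagged`.
#' @export
estimate_section_offsets <- function(strips, search_radius_px = 10L,
                                     row_radius_px = 3L) {
  if (length(strips) < 2L)
    return(tibble::tibble(pair = integer(), d_row = integer(),
                          d_col = integer(), score = numeric(),
                          flagged = logical()))
  rows <- lapply(seq_len(length(strips) - 1L), function(i) {
    est <- estimate_offset(strips[[i]], strips[[i + 1L]],
                           search_radius_px, row_radius_px)
    dplyr::mutate(est, pair = i)
  })
  dplyr::bind_rows(rows)[, c("pair", "d_row", "d_col", "score", "flagged")]
}

#' Stitch strips of one section into a complete section image
#'
#' Places strips left to right at cumulative pairwise offsets and removes the
#' duplicated overlap. With policy `"cut"` each overlap zone is split at its
#' midpoint, the left strip kept up to it and the right strip from it (pixels
#' are copied unmodified, so noise-free round trips are bit-exact); with
#' `"feather"` the zone is blended linearly. The output height is the
#' intersection of the vertically aligned rows.
#'
#' @param strips list of [strip_image][emit_strips] objects, ordered.
#' @param offsets tibble or data frame with `d_row`, `d_col` for each
#'   consecutive pair (one fewer row than strips), e.g. from
#'   [estimate_section_offsets()] or the phantom's `true_offsets`.
#' @param policy `"cut"` or `"feather"`.
#' @return a `section_image`: list with `pixels` (y, x matrix),
#'   `section_index`, `channel`, `pixel_size_um` and `provenance` (tibble of
#'   strip index and the column range it contributed; the ranges partition
#'   the section width).
#' @export
stitch_section <- function(strips, offsets = NULL, policy = c("cut", "feather")) {
  policy <- match.arg(policy)
  n <- length(strips)
  if (n == 0L) stop("no strips supplied", call. = FALSE)
  px <- lapply(strips, function(s) if (inherits(s, "strip_image")) s$pixels else s)
  meta <- strips[[1L]]
  if (!inherits(meta, "strip_image"))
    meta <- list(section_index = NA_integer_, channel = NA_character_,
                 pixel_size_um = c(NA_real_, NA_real_))

  if (n == 1L) {
    return(structure(list(pixels = px[[1L]],
                          section_index = meta$section_index,
                          channel = meta$channel,
                          pixel_size_um = meta$pixel_size_um,
                          row_origin = 0L,
                          provenance = tibble::tibble(strip_index = 1L,
                                                      col_start = 1L,
                                                      col_end = ncol(px[[1L]]))),
                     class = "section_image"))
  }
  if (is.null(offsets) || nrow(offsets) != n - 1L)
    stop("offsets must have one row per adjacent strip pair", call. = FALSE)

  pos_col <- c(0L, cumsum(as.integer(offsets$d_col)))
  pos_row <- c(0L, cumsum(as.integer(offsets$d_row)))
  widths <- vapply(px, ncol, integer(1))
  heights <- vapply(px, nrow, integer(1))
  for (i in seq_len(n - 1L)) {
    ov <- widths[i] - as.integer(offsets$d_col[i])
    if (ov < 0L)
      stop(sprintf("negative overlap (gap) between strips %d and %d", i, i + 1L),
           call. = FALSE)
  }
  width <- pos_col[n] + widths[n]
  r0 <- max(pos_row)                 # global row of first output row - 1
  r1 <- min(pos_row + heights)       # global row of last output row
  if (r1 <= r0) stop("strips share no common rows after vertical alignment",
                     call. = FALSE)
  height <- r1 - r0

  canvas <- matrix(0, height, width)
  weight <- matrix(0, height, width)

  # exclusive column ranges under the cut policy (overlap split at midpoint)
  cut_start <- integer(n); cut_end <- integer(n)
  cut_start[1L] <- 1L
  for (i in seq_len(n - 1L)) {
    ov <- widths[i] - as.integer(offsets$d_col[i])
    mid <- pos_col[i + 1L] + floor(ov / 2)
    cut_end[i] <- mid
    cut_start[i + 1L] <- mid + 1L
  }
  cut_end[n] <- width

  for (i in seq_len(n)) {
    rows_local <- (r0 - pos_row[i] + 1L):(r1 - pos_row[i])
    block <- px[[i]][rows_local, , drop = FALSE]
    if (policy == "cut") {
      cols_global <- cut_start[i]:cut_end[i]
      cols_local <- cols_global - pos_col[i]
      canvas[, cols_global] <- block[, cols_local, drop = FALSE]
    } else {
      cols_global <- (pos_col[i] + 1L):(pos_col[i] + widths[i])
      w <- rep(1, widths[i])
      if (i > 1L) {                      # ramp up over the left overlap zone
        ov <- widths[i - 1L] - as.integer(offsets$d_col[i - 1L])
        if (ov > 0L) w[seq_len(ov)] <- seq_len(ov) / (ov + 1)
      }
      if (i < n) {                       # ramp down over the right overlap zone
        ov <- widths[i] - as.integer(offsets$d_col[i])
        if (ov > 0L) w[widths[i] - ov + seq_len(ov)] <- rev(seq_len(ov)) / (ov + 1)
      }
      canvas[, cols_global] <- canvas[, cols_global] +
        sweep(block, 2L, w, `*`)
      weight[, cols_global] <- weight[, cols_global] + matrix(w, height, widths[i], byrow = TRUE)
    }
  }
  if (policy == "feather") {
    weight[weight == 0] <- 1
    canvas <- canvas / weight
  }
  pixels <- if (policy == "cut") canvas else {
    out <- as.integer(clip_u16(round(canvas)))
    dim(out) <- dim(canvas)
    out
  }
  if (policy == "cut" && is.integer(px[[1L]])) storage.mode(pixels) <- "integer"

  structure(list(pixels = pixels,
                 section_index = meta$section_index,
                 channel = meta$channel,
                 pixel_size_um = meta$pixel_size_um,
                 row_origin = r0,   # first output row relative to strip-1 frame
                 provenance = tibble::tibble(strip_index = seq_len(n),
                                             col_start = cut_start,
                                             col_end = cut_end)),
            class = "section_image")
}

#' @method print section_image
#' @export
print.section_image <- function(x, ...) {
  cat("<section_image> section", x$section_index,
      sprintf("(%d x %d px, %s, %d strips)\n", nrow(x$pixels), ncol(x$pixels),
              x$channel, nrow(x$provenance)))
  invisible(x)
}

#' Stitch every section of an emitted strip set
#'
#' Convenience wrapper running [estimate_section_offsets()] (or using supplied
#' true offsets) and [stitch_section()] per section.
#'
#' @param emitted result of [emit_strips()], or a bare list of strips.
#' @param offsets optional tibble (section, pair, d_row, d_col) of known
#'   offsets; when `NULL` offsets are estimated.
#' @param policy overlap policy, see [stitch_section()].
#' @param search_radius_px,row_radius_px search window for estimation.
#' @return list with `sections` (list of `section_image` by z) and `offsets`
#'   (tibble: section, pair, d_row, d_col, score).
#' @export
stitch_sections <- function(emitted, offsets = NULL, policy = "cut",
                            search_radius_px = 10L, row_radius_px = 3L) {
  strips <- if (is.list(emitted) && !is.null(emitted$strips)) emitted$strips else emitted
  secs <- split(strips, vapply(strips, function(s) s$section_index, integer(1)))
  out_off <- list()
  sections <- lapply(names(secs), function(zi) {
    ss <- secs[[zi]]
    ss <- ss[order(vapply(ss, function(s) s$strip_index, integer(1)))]
    off <- if (is.null(offsets)) {
      estimate_section_offsets(ss, search_radius_px, row_radius_px)
    } else {
      o <- offsets[offsets$section == as.integer(zi), , drop = FALSE]
      if (!"score" %in% names(o)) o$score <- NA_real_
      o
    }
    out_off[[zi]] <<- dplyr::mutate(off, section = as.integer(zi))
    stitch_section(ss, off, policy)
  })
  zord <- order(as.integer(names(secs)))
  off_tb <- dplyr::bind_rows(out_off)
  if (nrow(off_tb)) off_tb <- dplyr::arrange(off_tb, section, pair)
  list(sections = sections[zord], offsets = off_tb)
}
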