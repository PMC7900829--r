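#' Read a grayscale image sequence
#'
#' Accepts a multi-page TIFF file or a directory of numbered PNG frames
#' (sorted by file name). TIFF pixel data is returned at its stored integer
#' range (8- or 16-bit preserved as written); PNG frames are scaled to the
#' 0-255 gray range. All frames must share one size.
#'
#' @param path TIFF file or PNG directory.
#' @param mm_per_px Calibration to carry on the sequence.
#' @return A `vein_sequence`.
#' @export
read_sequence <- function(path, mm_per_px = 0.1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) abort(sprintf("No PNG frames found in '%s'.", path))
    frames <- purrr::map(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m * 255
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- purrr::map(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      storage.mode(m) <- "double"
      m
    })
  } else {
    abort(sprintf("No sequence found at '%s'.", path))
  }
  new_vein_sequence(frames, mm_per_px = mm_per_px)
}

#' Write a sequence as a multi-page TIFF
#'
#' Frames are rounded to integers and stored at the requested bit depth
#' (8 or 16); for frames already holding integer gray values in range the
#' round trip through [read_sequence()] is exact.
#'
#' @param seq A `vein_sequence`.
#' @param path Output `.tif` path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, bits = 16) {
  stopifnot(inherits(seq, "vein_sequence"))
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  top <- 2^bits - 1
  pages <- purrr::map(seq$frames, function(m) {
    m <- pmin(pmax(round(m), 0), top)
    m / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Write a binary mask as PNG (0/255)
#'
#' @param mask Binary matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0.5) * 1.0, path)
  invisible(path)
}

#' Read and write polyline region annotations
#'
#' Polylines are exchanged as JSON:
#' `{"regions": [{"id": "r1", "vertices": [[row, col], ...]}, ...]}` with
#' 1-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return `read_polylines`: a named list of [polyline()] objects.
#' @export
read_polylines <- function(path) {
  if (!file.exists(path)) abort(sprintf("Polyline file '%s' not found.", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$regions)) abort("Polyline JSON must contain a 'regions' array.")
  regions <- doc$regions
  out <- list()
  for (i in seq_len(nrow(regions))) {
    verts <- regions$vertices[[i]]
    out[[as.character(regions$id[i])]] <- polyline(verts)
  }
  out
}

#' @rdname read_polylines
#' @param regions Named list of polylines.
#' @export
write_polylines <- function(regions, path) {
  payload <- list(regions = purrr::imap(regions, function(v, id) {
    list(id = id, vertices = unclass(v))
  }))
  names(payload$regions) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write cohort tables
#'
#' A cohort is two CSV tables: a time-series table
#' (`subject_id, t_min, tskin_c, vd_mm`) and a baseline/subjects table
#' (`subject_id, tskin_ini_c, vd_ini_mm, tskin_fin_c, vd_fin_mm, group,
#' study`).
#'
#' @param cohort A `vein_cohort`.
#' @param series_path,subjects_path CSV paths.
#' @return `read_cohort`: a `vein_cohort` (without generator parameters).
#' @export
write_cohort <- function(cohort, series_path, subjects_path) {
  stopifnot(inherits(cohort, "vein_cohort"))
  readr::write_csv(cohort$series, series_path)
  readr::write_csv(cohort$subjects, subjects_path)
  invisible(series_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(series_path, subjects_path) {
  series <- readr::read_csv(series_path, show_col_types = FALSE)
  subjects <- readr::read_csv(subjects_path, show_col_types = FALSE)
  structure(
    list(subjects = subjects, series = series, params = NULL),
    class = "vein_cohort"
  )
}
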