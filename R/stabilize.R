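#' Rectangular region of interest
#'
#' 1-based inclusive pixel rectangle used as the block-matching block and as
#' the profile-uniformity box. Pick a region containing a high-contrast edge
#' (the dark fiducial mark is ideal): featureless blocks make every candidate
#' displacement score the same.
#'
#' @param row,col Top-left corner (1-based).
#' @param height,width Extent in pixels.
#' @return An object of class `vein_roi`.
#' @export
roi <- function(row, col, height, width) {
  if (height < 1 || width < 1) abort("ROI must have positive size.")
  if (row < 1 || col < 1) abort("ROI origin must be >= 1.")
  structure(
    list(
      row = as.integer(row), col = as.integer(col),
      height = as.integer(height), width = as.integer(width)
    ),
    class = "vein_roi"
  )
}

roi_block <- function(image, r, dy = 0, dx = 0) {
  image[
    seq(r$row + dy, r$row + r$height - 1L + dy),
    seq(r$col + dx, r$col + r$width - 1L + dx),
    drop = FALSE
  ]
}

check_roi_inside <- function(image, r, margin = 0L) {
  if (r$row - margin < 1L || r$col - margin < 1L ||
    r$row + r$height - 1L + margin > nrow(image) ||
    r$col + r$width - 1L + margin > ncol(image)) {
    abort("ROI (plus search radius) exceeds the frame bounds.")
  }
}

#' Estimate frame translation by exhaustive-search block matching
#'
#' Scans every integer displacement with `|dy|, |dx| <= search_radius` and
#' returns the one minimizing the sum of absolute differences (SAD) between
#' the reference ROI block and the displaced block in `frame`. Ties are
#' broken by the smallest L2 norm of the displacement, then row-major order.
#' The returned offset is the apparent motion of the frame content relative
#' to the reference: a frame whose content moved down 5 px and right 3 px
#' yields `(dy, dx) = (5, 3)`.
#'
#' @param frame,reference Numeric matrices of equal size.
#' @param block A [roi()] containing a high-contrast feature, placed so that
#'   `block` expanded by `search_radius` stays inside both frames.
#' @param search_radius Maximum displacement magnitude per axis, px (>= 0).
#' @return A one-row tibble: `dy`, `dx`, `sad` (score at the optimum),
#'   `degenerate` (TRUE when every candidate scored the same, e.g. on
#'   featureless frames — also raises a warning).
#' @export
estimate_translation <- function(frame, reference, block, search_radius = 15) {
  if (search_radius < 0) abort("`search_radius` must be >= 0.")
  if (!all(dim(frame) == dim(reference))) abort("Frame sizes differ.")
  check_roi_inside(reference, block)
  check_roi_inside(frame, block, margin = as.integer(search_radius))
  ref_block <- roi_block(reference, block)
  offsets <- seq(-search_radius, search_radius)
  best <- NULL
  max_sad <- -Inf
  # row-major scan; strict improvement rules keep earlier candidates on ties
  for (dy in offsets) {
    for (dx in offsets) {
      sad <- sum(abs(roi_block(frame, block, dy, dx) - ref_block))
      max_sad <- max(max_sad, sad)
      l2 <- dy * dy + dx * dx
      if (is.null(best) || sad < best$sad - 1e-9 ||
        (abs(sad - best$sad) <= 1e-9 && l2 < best$l2)) {
        best <- list(dy = dy, dx = dx, sad = sad, l2 = l2)
      }
    }
  }
  scores_equal <- (max_sad - best$sad) <= 1e-9
  if (scores_equal && search_radius > 0) {
    warn("Block matching is degenerate: every candidate displacement scores the same.")
  }
  tibble::tibble(
    dy = best$dy, dx = best$dx, sad = best$sad,
    degenerate = scores_equal && search_radius > 0
  )
}

#' Translate an image raster
#'
#' Integer offsets are exact index shifts; real-valued offsets use bilinear
#' resampling. Pixels exposed at the borders are filled with `fill`.
#'
#' @param image Numeric matrix.
#' @param dy,dx Offset applied to the content (positive = down/right).
#' @param fill Value for exposed pixels (default: image median).
#' @return A numeric matrix of the same size.
#' @export
translate_image <- function(image, dy, dx, fill = median(image)) {
  h <- nrow(image)
  w <- ncol(image)
  out <- matrix(fill, h, w)
  if (dy == round(dy) && dx == round(dx)) {
    dy <- as.integer(round(dy))
    dx <- as.integer(round(dx))
    src_r <- seq_len(h) - dy
    src_c <- seq_len(w) - dx
    ok_r <- src_r >= 1L & src_r <= h
    ok_c <- src_c >= 1L & src_c <= w
    out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c], drop = FALSE]
    return(out)
  }
  rr <- rep(seq_len(h), times = w) - dy
  cc <- rep(seq_len(w), each = h) - dx
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  vals <- rep(fill, h * w)
  vals[ok] <- bilinear_sample(image, rr[ok], cc[ok])
  matrix(vals, h, w)
}

#' Stabilize a sequence by block matching against the first frame
#'
#' The first frame is the reference. Each subsequent frame's translation is
#' estimated with [estimate_translation()] and undone by translating the
#' frame by the negated offset, preserving the original frame size; exposed
#' border pixels are filled with `pad` (default: the median gray of the
#' reference frame, a robust stand-in for the skin background).
#'
#' @param seq A `vein_sequence` (see [render_sequence()], [read_sequence()]).
#' @param block A [roi()] with a high-contrast feature, inside all frames
#'   with a `search_radius` margin.
#' @param search_radius Maximum displacement per axis, px.
#' @param pad Fill value for exposed pixels.
#' @return A list with `aligned` (a `vein_sequence`) and `motion` (tibble:
#'   `frame`, `dy`, `dx`, `sad`, `degenerate`).
#' @export
align_sequence <- function(seq, block, search_radius = 15, pad = NULL) {
  stopifnot(inherits(seq, "vein_sequence"))
  n <- length(seq$frames)
  reference <- seq$frames[[1]]
  if (is.null(pad)) pad <- median(reference)
  est <- vector("list", n)
  aligned <- vector("list", n)
  est[[1]] <- tibble::tibble(dy = 0L, dx = 0L, sad = 0, degenerate = FALSE)
  aligned[[1]] <- reference
  for (k in seq_len(n)[-1]) {
    e <- estimate_translation(seq$frames[[k]], reference, block, search_radius)
    est[[k]] <- e
    aligned[[k]] <- translate_image(seq$frames[[k]], -e$dy, -e$dx, fill = pad)
  }
  motion <- dplyr::bind_rows(est)
  motion <- dplyr::mutate(motion, frame = dplyr::row_number(), .before = 1)
  out <- new_vein_sequence(aligned,
    mm_per_px = seq$mm_per_px,
    truth = seq$truth, spec = seq$spec
  )
  list(aligned = out, motion = motion)
}

#' Normalized profile-uniformity QC of a stabilized sequence
#'
#' Reproduces the stabilization quality check: inside a box centred on the
#' dark fiducial mark, each frame's column-mean intensity profile is min-max
#' normalized; on a well-aligned sequence the per-frame profiles coincide.
#' The dispersion score is the mean, across positions, of the across-frame
#' standard deviation of the normalized profiles — 0 for identical frames,
#' and smaller after alignment than before on a jittered sequence.
#'
#' @param seq A `vein_sequence`.
#' @param box A [roi()] containing the fiducial mark.
#' @return A list with `profiles` (tibble: `frame`, `position`, `value`) and
#'   `dispersion` (scalar).
#' @export
profile_uniformity <- function(seq, box) {
  stopifnot(inherits(seq, "vein_sequence"))
  check_roi_inside(seq$frames[[1]], box)
  prof <- purrr::map(seq$frames, function(fr) {
    p <- colMeans(roi_block(fr, box))
    rng <- range(p)
    if (diff(rng) == 0) rep(0, length(p)) else (p - rng[1]) / diff(rng)
  })
  mat <- do.call(rbind, prof) # frames x positions
  dispersion <- if (nrow(mat) < 2L) 0 else mean(apply(mat, 2, sd))
  profiles <- tibble::tibble(
    frame = rep(seq_along(prof), each = ncol(mat)),
    position = rep(seq_len(ncol(mat)), times = nrow(mat)),
    value = as.vector(t(mat))
  )
  list(profiles = profiles, dispersion = dispersion)
}
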