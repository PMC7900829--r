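#' Describe a synthetic NIR hand scene
#'
#' A scene specification holds everything needed to render noise-controlled
#' near-infrared-like frames with known ground truth: dark curvilinear vessels
#' with Gaussian absorption cross-sections on a bright reflective background,
#' plus a dark fiducial mark used downstream as a high-contrast stabilization
#' anchor. The full width at half maximum (FWHM) of each rendered intensity
#' dip equals the vessel's nominal diameter, so the scene doubles as ground
#' truth for the calliper.
#'
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param mm_per_px Spatial calibration, millimetres per pixel (> 0).
#' @param vessels List of vessels built with [vessel()].
#' @param background_level Background gray value (reflective skin).
#' @param fiducial Optional fiducial built with [fiducial()]; must lie inside
#'   the image bounds.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise, in
#'   gray units. Applied last during rendering.
#' @param seed Integer seed governing the noise field; `NULL` leaves the
#'   caller's RNG untouched (only sensible with `noise_sigma = 0`).
#' @return An object of class `scene_spec`.
#' @seealso [render_frame()], [render_sequence()]
#' @export
#' @examples
#' sp <- scene_spec(
#'   image_size = c(64, 64),
#'   vessels = list(vessel(rbind(c(1, 32), c(64, 32)), diameter_mm = 2.3)),
#'   noise_sigma = 0
#' )
#' fr <- render_frame(sp)
#' dim(fr$image)
scene_spec <- function(image_size = c(256L, 256L), mm_per_px = 0.1,
                       vessels = list(), background_level = 200,
                       fiducial = NULL, noise_sigma = 0, seed = NULL) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size <= 0L)) {
    abort("`image_size` must be two positive integers (height, width).")
  }
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0) {
    abort("`mm_per_px` must be a single positive number.")
  }
  for (v in vessels) {
    if (!inherits(v, "vein_vessel")) {
      abort("Every element of `vessels` must be built with vessel().")
    }
    if (v$diameter_mm / mm_per_px > min(image_size)) {
      abort("Vessel diameter exceeds the image extent at this calibration.")
    }
  }
  if (!is.null(fiducial)) {
    if (!inherits(fiducial, "vein_fiducial")) {
      abort("`fiducial` must be built with fiducial().")
    }
    ctr <- fiducial$center
    if (any(ctr < 1) || ctr[1] > image_size[1] || ctr[2] > image_size[2]) {
      abort("Fiducial center must lie inside the image bounds.")
    }
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  structure(
    list(
      image_size = image_size, mm_per_px = mm_per_px, vessels = vessels,
      background_level = background_level, fiducial = fiducial,
      noise_sigma = noise_sigma,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d px @ %.3f mm/px, %d vessel(s), noise sigma %.2f\n",
    x$image_size[1], x$image_size[2], x$mm_per_px, length(x$vessels),
    x$noise_sigma
  ))
  invisible(x)
}

#' Define a synthetic vessel
#'
#' @param centerline Numeric matrix with one `(row, col)` vertex per row
#'   (1-based pixel coordinates), at least two distinct vertices.
#' @param diameter_mm Nominal vessel diameter in millimetres: the FWHM of the
#'   rendered absorption dip.
#' @param depth Peak absorption in gray units (how much darker the vessel
#'   axis is than the background).
#' @return An object of class `vein_vessel`.
#' @export
vessel <- function(centerline, diameter_mm, depth = 80) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L) {
    abort("`centerline` needs at least two (row, col) vertices.")
  }
  steps <- diff(centerline)
  if (any(rowSums(abs(steps)) == 0)) {
    abort("Consecutive centerline vertices must be distinct.")
  }
  if (diameter_mm <= 0) abort("`diameter_mm` must be positive.")
  structure(
    list(centerline = centerline, diameter_mm = diameter_mm, depth = depth),
    class = "vein_vessel"
  )
}

#' Define the dark fiducial mark
#'
#' The mark emulates the high-contrast skin marking drawn on the hand during
#' acquisition; it is rendered as a filled dark disk and anchors the
#' block-matching stabilization and its profile-uniformity QC.
#'
#' @param center `(row, col)` center in pixels.
#' @param radius Disk radius in pixels.
#' @param level Gray value of the disk (dark).
#' @return An object of class `vein_fiducial`.
#' @export
fiducial <- function(center, radius = 4, level = 20) {
  if (length(center) != 2L) abort("`center` must be (row, col).")
  if (radius <= 0) abort("`radius` must be positive.")
  structure(
    list(center = as.numeric(center), radius = radius, level = level),
    class = "vein_fiducial"
  )
}

# FWHM of a Gaussian is 2 sqrt(2 log 2) sigma; rendering works the other way
# round, from nominal diameter (the FWHM) to sigma.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Minimum distance from points (r, c) to a polyline, vectorized over points.
dist_to_polyline <- function(r, c, poly) {
  d2 <- rep(Inf, length(r))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]
    b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((r - a[1]) * ab[1] + (c - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dr <- r - (a[1] + t * ab[1])
    dc <- c - (a[2] + t * ab[2])
    d2 <- pmin(d2, dr^2 + dc^2)
  }
  sqrt(d2)
}

#' Render one synthetic NIR frame with ground truth
#'
#' Vessels appear as intensity dips with Gaussian cross-section whose FWHM in
#' pixels equals `dilation_scale * diameter_mm / mm_per_px`. The ground-truth
#' mask is 1 wherever a vessel's absorption exceeds half its peak, i.e.
#' within half an FWHM of the centerline. The fiducial is a filled dark disk.
#' Additive Gaussian noise (`noise_sigma`) is applied last under the seed.
#'
#' The translation is applied to the scene geometry (centerlines and fiducial
#' center), which is exact for real-valued offsets; raster translation of
#' already-rendered frames is the job of [translate_image()].
#'
#' @param spec A [scene_spec()].
#' @param dilation_scale Multiplier (>= 0) applied to every vessel diameter.
#' @param translation `(dy, dx)` offset in pixels applied to the scene
#'   content (positive moves content down/right).
#' @param rng_seed Seed for the noise field; defaults to `spec$seed`.
#' @return A list with `image` (numeric matrix, gray units) and `mask`
#'   (integer matrix, 1 = vessel).
#' @export
render_frame <- function(spec, dilation_scale = 1, translation = c(0, 0),
                         rng_seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (dilation_scale < 0) abort("`dilation_scale` must be >= 0.")
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  img <- matrix(spec$background_level, h, w)
  mask <- matrix(0L, h, w)
  for (v in spec$vessels) {
    fwhm_px <- dilation_scale * v$diameter_mm / spec$mm_per_px
    if (fwhm_px == 0) next
    sigma <- fwhm_to_sigma(fwhm_px)
    cl <- sweep(v$centerline, 2, translation, "+")
    d <- dist_to_polyline(rr, cc, cl)
    absorb <- v$depth * exp(-d^2 / (2 * sigma^2))
    img <- img - matrix(absorb, h, w)
    mask[matrix(d < fwhm_px / 2, h, w)] <- 1L
  }
  if (!is.null(spec$fiducial)) {
    f <- spec$fiducial
    ctr <- f$center + translation
    disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= f$radius^2
    img[matrix(disk, h, w)] <- f$level
  }
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(rng_seed, matrix(rnorm(h * w, 0, spec$noise_sigma), h, w))
  }
  list(image = img, mask = mask)
}

#' Per-frame translation track
#'
#' @param dy,dx Numeric vectors of per-frame offsets in pixels; frame 1 must
#'   be `(0, 0)` (the reference).
#' @return A tibble with columns `frame`, `dy`, `dx`.
#' @export
motion_track <- function(dy, dx) {
  if (length(dy) != length(dx)) abort("`dy` and `dx` must match in length.")
  if (length(dy) > 0 && (dy[1] != 0 || dx[1] != 0)) {
    abort("Frame 1 of a motion track is the reference and must be (0, 0).")
  }
  tibble::tibble(frame = seq_along(dy), dy = dy, dx = dx)
}

#' Per-frame dilation track
#'
#' @param scale Numeric vector of per-frame diameter scale factors (>= 0,
#'   finite); frame 1 must be 1, defining the baseline diameter.
#' @return A tibble with columns `frame`, `scale`.
#' @export
dilation_track <- function(scale) {
  if (length(scale) > 0 && scale[1] != 1) {
    abort("Frame 1 of a dilation track defines baseline and must be 1.")
  }
  if (any(!is.finite(scale)) || any(scale < 0)) {
    abort("Dilation scales must be finite and >= 0.")
  }
  tibble::tibble(frame = seq_along(scale), scale = scale)
}

#' Render an image sequence with per-frame ground truth
#'
#' Frame k is [render_frame()] at dilation `dilation$scale[k]`, with the scene
#' translated by `motion[k, ]`. Per-frame ground truth (true diameters in mm,
#' masks, injected motion) travels with the sequence so downstream stages can
#' be validated against it.
#'
#' @param spec A [scene_spec()].
#' @param motion A [motion_track()] (tibble with `dy`, `dx`) with one row per
#'   frame.
#' @param dilation A [dilation_track()] with the same number of rows.
#' @return A `vein_sequence`: list with `frames` (list of matrices), `masks`,
#'   `truth` (tibble: frame, dy, dx, scale, and per-vessel true diameter in
#'   mm), `mm_per_px`, and the generating `spec`.
#' @export
render_sequence <- function(spec, motion, dilation) {
  if (nrow(motion) != nrow(dilation)) {
    abort("Motion and dilation tracks must have the same number of frames.")
  }
  n <- nrow(motion)
  if (n == 0L) abort("Cannot render an empty sequence.")
  frames <- vector("list", n)
  masks <- vector("list", n)
  base_seed <- if (is.null(spec$seed)) NULL else spec$seed
  for (k in seq_len(n)) {
    fr <- render_frame(
      spec,
      dilation_scale = dilation$scale[k],
      translation = c(motion$dy[k], motion$dx[k]),
      rng_seed = if (is.null(base_seed)) NULL else base_seed + k
    )
    frames[[k]] <- fr$image
    masks[[k]] <- fr$mask
  }
  diam <- purrr::map(spec$vessels, function(v) v$diameter_mm)
  truth <- tibble::tibble(
    frame = seq_len(n), dy = motion$dy, dx = motion$dx,
    scale = dilation$scale
  )
  for (i in seq_along(diam)) {
    truth[[paste0("diameter_mm_v", i)]] <- diam[[i]] * dilation$scale
  }
  new_vein_sequence(frames,
    mm_per_px = spec$mm_per_px, masks = masks,
    truth = truth, spec = spec
  )
}

#' Construct an image sequence container
#'
#' @param frames List of equally sized numeric matrices (grayscale frames).
#' @param mm_per_px Spatial calibration carried with the sequence.
#' @param masks Optional list of ground-truth masks.
#' @param truth Optional tibble of per-frame ground truth.
#' @param spec Optional generating [scene_spec()].
#' @return An object of class `vein_sequence`.
#' @export
new_vein_sequence <- function(frames, mm_per_px = NA_real_, masks = NULL,
                              truth = NULL, spec = NULL) {
  if (length(frames) == 0L) abort("A sequence needs at least one frame.")
  dims <- purrr::map(frames, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    abort("All frames in a sequence must share the same dimensions.")
  }
  structure(
    list(
      frames = frames, mm_per_px = mm_per_px, masks = masks,
      truth = truth, spec = spec
    ),
    class = "vein_sequence"
  )
}

#' @export
print.vein_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<vein_sequence> %d frame(s) of %d x %d px @ %s mm/px%s\n",
    length(x$frames), d[1], d[2],
    ifelse(is.na(x$mm_per_px), "?", format(x$mm_per_px)),
    if (!is.null(x$truth)) " (with ground truth)" else ""
  ))
  invisible(x)
}

#' @export
length.vein_sequence <- function(x) length(x$frames)
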