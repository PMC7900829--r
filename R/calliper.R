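#' Validate a polyline
#'
#' Polylines are the user's (or ground truth's) assertion of where a vein
#' runs: ordered `(row, col)` vertices in 1-based pixel coordinates. The
#' calliper slices the image perpendicular to the polyline and measures the
#' vein diameter as the FWHM of each inverted cross-section.
#'
#' @param vertices Numeric matrix, one `(row, col)` vertex per row; at least
#'   two, consecutive vertices distinct.
#' @return The vertex matrix with class `vein_polyline`.
#' @export
polyline <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L) {
    abort("A polyline needs at least two (row, col) vertices.")
  }
  if (any(rowSums(abs(diff(vertices))) == 0)) {
    abort("Consecutive polyline vertices must be distinct.")
  }
  structure(vertices, class = c("vein_polyline", "matrix"))
}

# Bilinear interpolation of image values at real-valued (r, c); errors if any
# sample point falls outside the image.
bilinear_sample <- function(image, r, c) {
  h <- nrow(image)
  w <- ncol(image)
  if (any(r < 1 - 1e-9) || any(r > h + 1e-9) ||
    any(c < 1 - 1e-9) || any(c > w + 1e-9)) {
    abort("Sample points fall outside the image.")
  }
  r <- pmin(pmax(r, 1), h)
  c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1L)
  c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- image[cbind(r0, c0)]
  i10 <- image[cbind(r0 + 1, c0)]
  i01 <- image[cbind(r0, c0 + 1)]
  i11 <- image[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# Position and unit tangent of a polyline at arc length s. Tangents are the
# local segment direction; at interior vertices the two adjacent segment
# directions are averaged (central difference); endpoints use the one-sided
# segment.
polyline_point <- function(vertices, s) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  n <- length(s)
  pos <- matrix(0, n, 2)
  tan <- matrix(0, n, 2)
  eps <- 1e-9
  for (j in seq_len(n)) {
    i <- max(which(cum <= s[j] + eps))
    i <- min(i, nrow(seg))
    t <- (s[j] - cum[i]) / seg_len[i]
    pos[j, ] <- vertices[i, ] + t * seg[i, ]
    at_vertex <- abs(s[j] - cum[i]) < eps || abs(s[j] - cum[i + 1]) < eps
    k <- if (abs(s[j] - cum[i + 1]) < eps) i + 1L else i
    if (at_vertex && k > 1L && k <= nrow(seg)) {
      d <- seg[k - 1L, ] / seg_len[k - 1L] + seg[k, ] / seg_len[k]
    } else {
      d <- seg[i, ] / seg_len[i]
    }
    tan[j, ] <- d / sqrt(sum(d^2))
  }
  list(position = pos, tangent = tan, total_length = total)
}

#' Sample perpendicular intensity profiles along a polyline
#'
#' Slice centers are placed every `spacing` pixels of arc length (including
#' both endpoints). Each slice samples the image by bilinear interpolation
#' along the local perpendicular at 1-px steps, `2 * half_length + 1` samples
#' centred on the polyline.
#'
#' @param image Numeric matrix (grayscale frame).
#' @param line A [polyline()] (or bare vertex matrix).
#' @param spacing Arc-length distance between slice centers, px.
#' @param half_length Half-extent of each slice, px (> 0); the polyline must
#'   keep this margin from the image border.
#' @return A tibble with one row per slice: `slice`, `s` (arc length of the
#'   center), `center_r`, `center_c`, `normal_r`, `normal_c`, and `profile`
#'   (list-column of numeric vectors).
#' @export
slice_profiles <- function(image, line, spacing = 2, half_length = 15) {
  if (half_length <= 0) abort("`half_length` must be positive.")
  if (spacing <= 0) abort("`spacing` must be positive.")
  vertices <- unclass(line)
  geo <- polyline_point(vertices, 0)
  total <- geo$total_length
  s <- seq(0, total, by = spacing)
  if (abs(s[length(s)] - total) > 1e-9) s <- c(s, total)
  pt <- polyline_point(vertices, s)
  normal <- cbind(-pt$tangent[, 2], pt$tangent[, 1])
  offs <- seq(-half_length, half_length)
  profiles <- vector("list", length(s))
  for (j in seq_along(s)) {
    rr <- pt$position[j, 1] + offs * normal[j, 1]
    cc <- pt$position[j, 2] + offs * normal[j, 2]
    if (any(rr < 1) || any(rr > nrow(image)) ||
      any(cc < 1) || any(cc > ncol(image))) {
      abort("Polyline slice exits the image; shrink half_length or move the polyline.")
    }
    profiles[[j]] <- bilinear_sample(image, rr, cc)
  }
  tibble::tibble(
    slice = seq_along(s), s = s,
    center_r = pt$position[, 1], center_c = pt$position[, 2],
    normal_r = normal[, 1], normal_c = normal[, 2],
    profile = profiles
  )
}

# Local maxima of a numeric vector, plateaus collapsed to their center.
local_maxima <- function(z) {
  n <- length(z)
  if (n < 3L) {
    return(integer(0))
  }
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (z[i] > z[i - 1L] && z[i] >= z[i + 1L]) {
      j <- i
      while (j < n && z[j + 1L] == z[i]) j <- j + 1L
      if (j == n || z[j + 1L] < z[i]) {
        peaks <- c(peaks, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

#' Full width at half maximum of an inverted intensity profile
#'
#' The vein appears as an intensity dip, so the profile is inverted and the
#' dip becomes a peak. The baseline is the mean of the outer 10% of samples
#' at each end; the half-maximum level sits halfway between baseline and peak.
#' The width is the distance between the two half-maximum crossings flanking
#' the peak, each located by linear interpolation between bracketing samples.
#' With several candidate peaks the one nearest the slice center wins, ties
#' going to the higher prominence.
#'
#' A slice can be *rejected* rather than erroring: when no peak rises at
#' least `contrast_floor` gray units above baseline, or when a half-maximum
#' crossing is not bracketed within the profile. Rejections carry a reason.
#'
#' @param profile Numeric vector of intensity samples (>= 5), or a one-row
#'   slice from [slice_profiles()].
#' @param contrast_floor Minimum peak prominence above baseline, gray units.
#' @param sample_spacing Distance between consecutive samples in px.
#' @return A one-row tibble: `width_px`, `peak_index`, `prominence`,
#'   `rejected`, `reason`.
#' @export
#' @examples
#' x <- seq(-15, 15)
#' dip <- 200 - 80 * exp(-x^2 / (2 * 2^2)) # sigma = 2 px
#' fwhm(dip) # ~ 2 * sqrt(2 * log(2)) * 2 = 4.71 px
fwhm <- function(profile, contrast_floor = 5, sample_spacing = 1) {
  y <- as.numeric(profile)
  n <- length(y)
  if (n < 5L) abort("A profile needs at least 5 samples.")
  z <- -y
  k <- max(1L, ceiling(0.1 * n))
  baseline <- mean(c(z[seq_len(k)], z[seq(n - k + 1L, n)]))
  reject <- function(reason) {
    tibble::tibble(
      width_px = NA_real_, peak_index = NA_integer_,
      prominence = NA_real_, rejected = TRUE, reason = reason
    )
  }
  peaks <- local_maxima(z)
  prom <- z[peaks] - baseline
  peaks <- peaks[prom >= contrast_floor]
  prom <- prom[prom >= contrast_floor]
  if (length(peaks) == 0L) {
    return(reject("no peak"))
  }
  center <- (n + 1) / 2
  dist <- abs(peaks - center)
  best <- which(dist == min(dist))
  if (length(best) > 1L) best <- best[which.max(prom[best])]
  p <- peaks[best]
  half <- baseline + (z[p] - baseline) / 2
  # walk outwards from the peak to the first samples below the half level
  left <- NA_real_
  for (i in seq(p - 1L, 1L)) {
    if (z[i] < half) {
      left <- i + (half - z[i]) / (z[i + 1L] - z[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(p + 1L, n)) {
    if (z[i] < half) {
      right <- i - (half - z[i]) / (z[i - 1L] - z[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    return(reject("half-maximum crossing not bracketed"))
  }
  tibble::tibble(
    width_px = (right - left) * sample_spacing,
    peak_index = as.integer(p),
    prominence = z[p] - baseline, rejected = FALSE, reason = NA_character_
  )
}

#' Measure the mean vein diameter of a polyline region
#'
#' Runs [fwhm()] on every perpendicular slice along the polyline and averages
#' the valid widths — the region's diameter is reported as the mean FWHM over
#' valid slices, in pixels and (via `mm_per_px`) millimetres. Rejected slices
#' are counted but excluded from the mean.
#'
#' @inheritParams slice_profiles
#' @inheritParams fwhm
#' @param mm_per_px Spatial calibration (mm per pixel).
#' @param region_id Optional label carried into the result.
#' @return A one-row tibble: `region`, `n_slices`, `n_valid`, `n_rejected`,
#'   `mean_px`, `sd_px`, `mean_mm`, `sd_mm`, plus a `slices` list-column with
#'   the per-slice table.
#' @export
measure_region <- function(image, line, spacing = 2, half_length = 15,
                           mm_per_px = 0.1, contrast_floor = 5,
                           region_id = "region1") {
  slices <- slice_profiles(image, line, spacing = spacing, half_length = half_length)
  res <- purrr::map(slices$profile, fwhm, contrast_floor = contrast_floor)
  res <- dplyr::bind_rows(res)
  per_slice <- dplyr::bind_cols(slices[c("slice", "s")], res)
  valid <- per_slice$width_px[!per_slice$rejected]
  if (length(valid) == 0L) {
    abort(sprintf("All %d slices of region '%s' were rejected.", nrow(per_slice), region_id))
  }
  tibble::tibble(
    region = region_id,
    n_slices = nrow(per_slice),
    n_valid = length(valid),
    n_rejected = sum(per_slice$rejected),
    mean_px = mean(valid),
    sd_px = ifelse(length(valid) > 1, sd(valid), 0),
    mean_mm = mean(valid) * mm_per_px,
    sd_mm = ifelse(length(valid) > 1, sd(valid) * mm_per_px, 0),
    slices = list(per_slice)
  )
}

#' Single-line (1D scan) vein diameter
#'
#' Measures the FWHM along one user-drawn line crossing the vein — the 1D
#' scan that a region average is compared against. The profile is sampled at
#' 1-px steps along the line itself.
#'
#' @param image Numeric matrix.
#' @param line Two-vertex [polyline()] crossing the vessel.
#' @param mm_per_px Spatial calibration (mm per pixel).
#' @inheritParams fwhm
#' @return A one-row tibble: `width_px`, `width_mm`, `rejected`, `reason`.
#' @export
single_line_diameter <- function(image, line, mm_per_px = 0.1,
                                 contrast_floor = 5) {
  vertices <- unclass(line)
  if (nrow(vertices) != 2L) abort("A 1D scan line has exactly two vertices.")
  len <- sqrt(sum((vertices[2, ] - vertices[1, ])^2))
  n <- max(5L, floor(len) + 1L)
  t <- seq(0, 1, length.out = n)
  rr <- vertices[1, 1] + t * (vertices[2, 1] - vertices[1, 1])
  cc <- vertices[1, 2] + t * (vertices[2, 2] - vertices[1, 2])
  prof <- bilinear_sample(image, rr, cc)
  res <- fwhm(prof, contrast_floor = contrast_floor, sample_spacing = len / (n - 1))
  tibble::tibble(
    width_px = res$width_px,
    width_mm = res$width_px * mm_per_px,
    rejected = res$rejected, reason = res$reason
  )
}
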