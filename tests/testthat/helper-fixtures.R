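# Shared synthetic fixtures. Everything is generated in code under explicit
# seeds; nothing is read from disk.

# A straight vertical vessel down the middle of the frame.
straight_scene <- function(size = 128L, diameter_mm = 3.0, mm_per_px = 0.1,
                           depth = 80, noise_sigma = 0, seed = NULL,
                           with_fiducial = FALSE) {
  scene_spec(
    image_size = c(size, size), mm_per_px = mm_per_px,
    vessels = list(vessel(
      rbind(c(1, size / 2), c(size, size / 2)),
      diameter_mm = diameter_mm, depth = depth
    )),
    fiducial = if (with_fiducial) fiducial(c(size / 4, size / 4), 4, 20) else NULL,
    noise_sigma = noise_sigma, seed = seed
  )
}

# The standard segmentation fixture family: 256x256 scenes with one or two
# curved vessels of varying diameter and depth plus a fiducial, light noise.
fixture_scene <- function(seed) {
  set.seed(seed)
  nv <- sample(1:2, 1)
  vessels <- lapply(seq_len(nv), function(i) {
    c0 <- runif(1, 60, 200)
    amp <- runif(1, -20, 20)
    rs <- seq(10, 246, length.out = 7)
    cl <- cbind(rs, c0 + amp * sin(seq(0, pi, length.out = 7)) + (i - 1) * 60)
    cl[, 2] <- pmin(pmax(cl[, 2], 30), 226)
    vessel(cl, diameter_mm = runif(1, 1.5, 3.5), depth = runif(1, 60, 100))
  })
  scene_spec(c(256L, 256L),
    vessels = vessels,
    fiducial = fiducial(c(30, 30), 4, 20),
    noise_sigma = 2, seed = seed
  )
}

fixture_frames <- function(seeds) {
  lapply(seeds, function(s) render_frame(fixture_scene(s), rng_seed = s))
}

# Train the standard fixture network (16 train scenes, depth 2, base 8,
# 20 epochs) once per test session and reuse it everywhere.
trained_fixture_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- fixture_frames(1:16)
      cfg <- segnet_config(
        depth = 2L, base_filters = 8L, epochs = 20L, seed = 42L
      )
      tr <- train_segnet(
        build_segnet(cfg),
        lapply(train, `[[`, "image"), lapply(train, `[[`, "mask")
      )
      cache <<- tr
    }
    cache
  }
})

# Brute-force cross-correlation oracle: the displacement of `frame` relative
# to `reference` that maximizes the correlation of a central template block.
brute_xcorr_shift <- function(frame, reference, radius = 15, margin = radius + 2) {
  h <- nrow(reference)
  w <- ncol(reference)
  rows <- (margin + 1):(h - margin)
  cols <- (margin + 1):(w - margin)
  tmpl <- reference[rows, cols]
  tmpl <- tmpl - mean(tmpl)
  best <- c(0, 0)
  best_score <- -Inf
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      cand <- frame[rows + dy, cols + dx]
      cand <- cand - mean(cand)
      score <- sum(tmpl * cand) / sqrt(sum(tmpl^2) * sum(cand^2) + 1e-12)
      if (score > best_score) {
        best_score <- score
        best <- c(dy, dx)
      }
    }
  }
  best
}

# Dense brute-force FWHM oracle: evaluate an analytic profile function on a
# 100x finer grid and scan for the background-referenced half-maximum
# crossings directly.
dense_fwhm_oracle <- function(profile_fn, half_length, step = 0.01) {
  x <- seq(-half_length, half_length, by = step)
  y <- profile_fn(x)
  z <- -y
  n <- length(z)
  k <- max(1L, ceiling(0.1 * n))
  baseline <- mean(c(z[seq_len(k)], z[seq(n - k + 1L, n)]))
  p <- which.max(z)
  half <- baseline + (z[p] - baseline) / 2
  left <- max(which(z[1:p] < half))
  right <- p - 1L + min(which(z[p:n] < half))
  (x[right] - x[left + 1L]) + step # crossing bracketed within one step
}
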