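test_that("slice geometry: centers every spacing px, normals perpendicular", {
  img <- matrix(100, 32, 32)
  sl <- slice_profiles(img, polyline(rbind(c(16, 10), c(16, 20))),
    spacing = 5, half_length = 4
  )
  expect_equal(nrow(sl), 3L)
  expect_equal(sl$s, c(0, 5, 10))
  # horizontal polyline -> vertical normals
  expect_equal(abs(sl$normal_r), rep(1, 3))
  expect_equal(sl$normal_c, rep(0, 3))
  # uniform image -> constant profiles
  for (p in sl$profile) expect_true(all(p == 100))
  expect_equal(length(sl$profile[[1]]), 9L)
})

test_that("slices across a synthetic vessel reproduce the analytic dip", {
  sp <- straight_scene(size = 128, diameter_mm = 3.0)
  fr <- render_frame(sp)
  sl <- slice_profiles(fr$image, polyline(rbind(c(40, 64), c(90, 64))),
    spacing = 10, half_length = 40
  )
  sigma <- 30 / (2 * sqrt(2 * log(2)))
  x <- seq(-40, 40)
  analytic <- 200 - 80 * exp(-x^2 / (2 * sigma^2))
  for (p in sl$profile) {
    expect_lt(max(abs(p - analytic)), 0.05) # bilinear interpolation error
  }
})

test_that("polylines that exit the image or bad parameters are rejected", {
  img <- matrix(0, 32, 32)
  expect_error(
    slice_profiles(img, polyline(rbind(c(2, 2), c(2, 30))), half_length = 5),
    "exits the image"
  )
  expect_error(
    slice_profiles(img, polyline(rbind(c(16, 2), c(16, 30))), half_length = 0),
    "positive"
  )
  expect_error(polyline(rbind(c(1, 1))), "two")
})

test_that("fwhm matches closed forms for Gaussian and rectangular dips", {
  x <- seq(-15, 15)
  gauss <- 200 - 80 * exp(-x^2 / (2 * 2^2))
  w <- fwhm(gauss)
  expect_false(w$rejected)
  expect_lt(abs(w$width_px - 2 * sqrt(2 * log(2)) * 2) / 4.7096, 0.01)

  rect <- rep(200, 31)
  rect[13:19] <- 100
  expect_equal(fwhm(rect)$width_px, 7, tolerance = 1e-9)

  flat <- fwhm(rep(150, 31))
  expect_true(flat$rejected)
  expect_equal(flat$reason, "no peak")
})

test_that("fwhm agrees with the dense brute-force oracle within 0.05 px", {
  for (sigma in c(2, 3, 5)) {
    fn <- function(x) 200 - 80 * exp(-x^2 / (2 * sigma^2))
    hl <- max(15, 5 * sigma)
    ours <- fwhm(fn(seq(-hl, hl)))$width_px
    oracle <- dense_fwhm_oracle(fn, hl)
    expect_lt(abs(ours - oracle), 0.05)
  }
})

test_that("half-maximum crossings outside the profile lead to rejection", {
  # skewed dip: the right flank decays so slowly it never reaches the
  # half-maximum level inside the window
  x <- seq(-10, 10)
  skew <- ifelse(x < 0, 200 - 80 * exp(-x^2 / 8), 200 - 80 * exp(-x^2 / 800))
  r <- fwhm(skew, contrast_floor = 1)
  expect_true(r$rejected)
  expect_match(r$reason, "not bracketed")
})

test_that("the nearest-to-center peak wins when several peaks exist", {
  x <- seq(-40, 40)
  two <- 200 - 60 * exp(-x^2 / 8) - 80 * exp(-(x - 20)^2 / 8)
  r <- fwhm(two)
  expect_false(r$rejected)
  # center peak (sigma = 2) selected although the off-center one is deeper
  expect_equal(r$peak_index, 41L)
  expect_lt(abs(r$width_px - 4.7096), 0.1)
})

test_that("measure_region recovers a straight vessel diameter within 1%", {
  sp <- straight_scene(size = 128, diameter_mm = 3.0)
  fr <- render_frame(sp)
  m <- measure_region(fr$image, polyline(rbind(c(40, 64), c(90, 64))),
    half_length = 45, mm_per_px = 0.1
  )
  expect_lt(abs(m$mean_mm - 3.0) / 3.0, 0.01)
  expect_lt(m$sd_px, 0.05)
  expect_equal(m$n_rejected, 0L)
})

test_that("a curved noisy vessel is measured within 5% of truth", {
  cl <- cbind(seq(20, 236, length.out = 7), 128 + 18 * sin(seq(0, pi, length.out = 7)))
  sp <- scene_spec(c(256L, 256L),
    vessels = list(vessel(cl, diameter_mm = 2.5, depth = 80)),
    noise_sigma = 2, seed = 31
  )
  fr <- render_frame(sp)
  m <- measure_region(fr$image, polyline(cl), half_length = 40, mm_per_px = 0.1)
  expect_lt(abs(m$mean_mm - 2.5) / 2.5, 0.05)
})

test_that("all-rejected regions raise an error naming the region", {
  img <- matrix(100, 64, 64)
  expect_error(
    measure_region(img, polyline(rbind(c(32, 10), c(32, 50))),
      half_length = 10, region_id = "r7"
    ),
    "r7"
  )
})

test_that("single-line scan equals the region mean on a uniform straight vessel", {
  sp <- straight_scene(size = 128, diameter_mm = 3.0)
  fr <- render_frame(sp)
  m <- measure_region(fr$image, polyline(rbind(c(40, 64), c(90, 64))),
    half_length = 45, mm_per_px = 0.1
  )
  s <- single_line_diameter(fr$image, polyline(rbind(c(64, 19), c(64, 109))),
    mm_per_px = 0.1
  )
  expect_false(s$rejected)
  expect_lt(abs(s$width_mm - m$mean_mm) / m$mean_mm, 0.01)
})

test_that("a line at the widest point of a tapered vessel exceeds the region mean", {
  # taper: two collinear segments, diameter interpolated by rendering two
  # overlapping vessels of different diameter at the two halves
  sp <- scene_spec(c(128L, 128L),
    vessels = list(
      vessel(rbind(c(1, 64), c(64, 64)), diameter_mm = 3.6, depth = 80),
      vessel(rbind(c(64, 64), c(128, 64)), diameter_mm = 2.4, depth = 80)
    ),
    noise_sigma = 0
  )
  fr <- render_frame(sp)
  m <- measure_region(fr$image, polyline(rbind(c(20, 64), c(108, 64))),
    half_length = 45, mm_per_px = 0.1
  )
  wide <- single_line_diameter(fr$image, polyline(rbind(c(30, 19), c(30, 109))),
    mm_per_px = 0.1
  )
  expect_gt(wide$width_mm, m$mean_mm)
})

test_that("a line missing the vessel is rejected, not an error", {
  sp <- straight_scene(size = 128, diameter_mm = 2.0)
  fr <- render_frame(sp)
  s <- single_line_diameter(fr$image, polyline(rbind(c(10, 100), c(50, 120))))
  expect_true(s$rejected)
})

test_that("diameter in mm is scale-equivariant under resampling calibration", {
  m1 <- measure_region(
    render_frame(straight_scene(size = 128, diameter_mm = 2.4, mm_per_px = 0.1))$image,
    polyline(rbind(c(40, 64), c(90, 64))),
    half_length = 40, mm_per_px = 0.1
  )
  m2 <- measure_region(
    render_frame(straight_scene(size = 256, diameter_mm = 2.4, mm_per_px = 0.05))$image,
    polyline(rbind(c(80, 128), c(180, 128))),
    half_length = 80, mm_per_px = 0.05
  )
  expect_lt(abs(m1$mean_mm - m2$mean_mm) / m1$mean_mm, 0.02)
})

test_that("diameter is invariant to a 30-degree scene rotation within 2%", {
  size <- 160
  ctr <- (size + 1) / 2
  ang <- 30 * pi / 180
  dir <- c(cos(ang), sin(ang))
  ends <- rbind(ctr + 70 * dir * c(-1, -1), ctr + 70 * dir)
  sp_rot <- scene_spec(c(size, size),
    vessels = list(vessel(ends, diameter_mm = 2.6, depth = 80)),
    noise_sigma = 0
  )
  guide <- rbind(ctr + 40 * dir * c(-1, -1), ctr + 40 * dir)
  m_rot <- measure_region(render_frame(sp_rot)$image, polyline(guide),
    half_length = 40, mm_per_px = 0.1
  )
  m_axis <- measure_region(
    render_frame(straight_scene(size = 160, diameter_mm = 2.6))$image,
    polyline(rbind(c(40, 80), c(120, 80))),
    half_length = 40, mm_per_px = 0.1
  )
  expect_lt(abs(m_rot$mean_mm - m_axis$mean_mm) / m_axis$mean_mm, 0.02)
})

test_that("measured diameter increases strictly with dilation", {
  sp <- straight_scene(size = 160, diameter_mm = 2.2)
  line <- polyline(rbind(c(50, 80), c(110, 80)))
  widths <- sapply(c(1.0, 1.2, 1.4), function(s) {
    measure_region(render_frame(sp, dilation_scale = s)$image, line,
      half_length = 50, mm_per_px = 0.1
    )$mean_mm
  })
  expect_true(all(diff(widths) > 0))
})
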