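test_that("percent dilation reproduces the printed study-A worked example", {
  # post-stimulus means 3.19..2.37 mm against the 2.29 mm baseline
  r <- percent_dv(c(3.19, 2.88, 2.58, 2.5, 2.37), vd_base = 2.29)
  expect_equal(r$increment_pct, 39.3, tolerance = 0.0013)
  # study-B printed means give 8.77% by the same arithmetic
  rb <- percent_dv(c(3.35, 3.3, 3.23, 3.11, 3.14), vd_base = 3.08)
  expect_equal(rb$increment_pct, 8.77, tolerance = 0.001)
})

test_that("percent dilation is scale invariant and handles the no-change case", {
  base <- percent_dv(c(3.19, 2.88, 2.37), 2.29)
  for (k in c(0.1, 2, 17)) {
    scaled <- percent_dv(k * c(3.19, 2.88, 2.37), k * 2.29)
    expect_equal(scaled$percent_dv, base$percent_dv)
  }
  expect_equal(percent_dv(rep(2.29, 5), 2.29)$increment_pct, 0)
  expect_error(percent_dv(c(1, 2), 0), "positive")
  expect_error(percent_dv(numeric(0), 1), "nonempty")
})

test_that("fit_decay recovers noise-free parameters to 1e-6 with R^2 = 1", {
  t <- seq(0, 6, by = 0.5)
  y <- 2.29 + 1.0 * exp(-t / 2.0)
  f <- fit_decay(t, y)
  expect_lt(abs(f$a - 1.0), 1e-6)
  expect_lt(abs(f$tau - 2.0), 1e-6)
  expect_lt(abs(f$c - 2.29), 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("fit_decay reports a constant series as degenerate, not an error", {
  f <- fit_decay(1:5, rep(3.1, 5))
  expect_true(f$degenerate)
  expect_equal(f$a, 0)
  expect_true(is.na(f$r_squared))
})

test_that("fit_decay reaches R^2 > 0.9 on the 1%-amplitude-noise fixture", {
  t <- seq(0, 5, by = 0.25)
  set.seed(12)
  y <- 31 + 4 * exp(-t / 1.8) + rnorm(length(t), 0, 0.04)
  f <- fit_decay(t, y)
  expect_gt(f$r_squared, 0.9)
})

test_that("fit_decay satisfies first-order optimality at the solution", {
  t <- seq(0, 5, by = 0.5)
  set.seed(4)
  y <- 2.3 + 0.9 * exp(-t / 1.5) + rnorm(length(t), 0, 0.02)
  f <- fit_decay(t, y)
  g_a <- exp(-t / f$tau)
  g_tau <- f$a * exp(-t / f$tau) * t / f$tau^2
  g_c <- rep(1, length(t))
  scale <- sum(abs(f$residuals))
  expect_lt(abs(sum(f$residuals * g_a)) / scale, 1e-5)
  expect_lt(abs(sum(f$residuals * g_tau)) / scale, 1e-5)
  expect_lt(abs(sum(f$residuals * g_c)) / scale, 1e-5)
})

test_that("fit_decay validates its inputs", {
  expect_error(fit_decay(1:3, 1:3), "at least 4")
  expect_error(fit_decay(c(1, 2, 2, 3), c(1, 2, 3, 4)), "strictly increasing")
})

test_that("diameter-temperature correlation handles exact and noisy lines", {
  tskin <- c(31, 32, 33, 34, 35)
  exact <- correlate_vd_tskin(tskin, 0.1 * tskin - 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 0.1)
  expect_error(correlate_vd_tskin(rep(33, 5), 1:5), "zero variance")
  set.seed(8)
  ts2 <- runif(30, 30, 37)
  noisy <- correlate_vd_tskin(ts2, 0.1 * ts2 - 1 + rnorm(30, 0, 0.01))
  expect_lt(abs(noisy$slope - 0.1) / 0.1, 0.05)
})

test_that("the prediction model inverts a noise-free generating cohort exactly", {
  coh <- simulate_cohort(cohort_params(n_subjects = 10, noise_sd = 0, seed = 3))
  m <- fit_prediction_model(coh, final_time = 5)
  expect_lt(max(abs(m$coefficients - c(-17.9, 0.28, 0.93, 0.37))), 1e-6)
  expect_equal(m$source, "fitted")
})

test_that("collinear or constant predictors are a rank-deficiency error", {
  df <- tibble::tibble(
    tskin_ini_c = rep(33, 8), vd_ini_mm = rep(2.3, 8),
    tskin_fin_c = rep(36, 8), vd_fin_mm = rnorm(8, 2.5, 0.1)
  )
  expect_error(fit_prediction_model(df), "rank deficient")
  expect_error(fit_prediction_model(df[1:4, ]), "at least 5")
})

test_that("a noisy cohort gives a plausible intermediate R^2", {
  coh <- simulate_cohort(cohort_params(
    n_subjects = 10, noise_sd = 0.42, seed = 21
  ))
  m <- fit_prediction_model(coh, final_time = 5)
  expect_gt(m$r_squared, 0.4)
  expect_lt(m$r_squared, 0.9)
})

test_that("predict_vd applies the linear form, including the published coefficients", {
  expect_equal(predict_vd(c(0, 0, 1, 0), 99, 2.5, 99)$vd_pred_mm, 2.5)
  expect_equal(predict_vd(c(-17.9, 0.28, 0.93, 0.37), 0, 0, 0)$vd_pred_mm, -17.9)
  p <- predict_vd(vd_model_published(), 33.0, 2.30, 36.0)
  expect_equal(p$vd_pred_mm, -17.9 + 0.28 * 33 + 0.93 * 2.3 + 0.37 * 36)
  expect_equal(p$vd_pred_mm, 6.799, tolerance = 1e-9)
  expect_equal(p$model_source, "published")
  expect_error(predict_vd(c(1, 2, NA, 4), 1, 1, 1), "finite")
})

test_that("bland_altman computes bias and 1.96-sd limits of agreement", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  ba <- bland_altman(c(1.1, 1.9), c(1.0, 2.0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sd(c(0.1, -0.1)))
  expect_equal(ba$loa_upper, 1.96 * 0.1414214, tolerance = 1e-4)
  expect_error(bland_altman(1:3, 1:2), "Lengths differ")
})

test_that("limits of agreement half-width tracks the residual sd", {
  coh <- simulate_cohort(cohort_params(n_subjects = 200, noise_sd = 0.3, seed = 6))
  m <- vd_model_published()
  pred <- predict_vd(
    m, coh$subjects$tskin_ini_c, coh$subjects$vd_ini_mm,
    coh$subjects$tskin_fin_c
  )$vd_pred_mm
  ba <- bland_altman(coh$subjects$vd_fin_mm, pred)
  half <- 1.96 * ba$sd_diff
  expect_lt(abs(half - 0.588) / 0.588, 0.15) # sampling error at n = 200
})

test_that("paired t-test conventions: all-zero differences, large effects, antisymmetry", {
  expect_equal(paired_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "Zero variance")
  set.seed(2)
  before <- rnorm(10, 2.3, 0.3)
  after <- before + 1 + rnorm(10, 0, 0.05)
  r <- paired_ttest(before, after)
  expect_lt(r$p_value, 0.001)
  r_swap <- paired_ttest(after, before)
  expect_equal(r_swap$t, -r$t)
  expect_equal(r_swap$p_value, r$p_value)
})

test_that("tidy and glance methods summarize the fitted objects", {
  f <- fit_decay(seq(0, 6, 0.5), 2.29 + exp(-seq(0, 6, 0.5) / 2))
  td <- tidy(f)
  expect_equal(td$term, c("a", "tau", "c"))
  expect_equal(glance(f)$r_squared, 1, tolerance = 1e-9)
  expect_named(
    augment(f), c("t", "y", ".fitted", ".resid")
  )
  coh <- simulate_cohort(cohort_params(n_subjects = 8, noise_sd = 0.1, seed = 5))
  m <- fit_prediction_model(coh)
  expect_equal(nrow(tidy(m)), 4L)
  expect_equal(glance(m)$n, 8L)
  expect_equal(nrow(tidy(vd_model_published())), 4L)
  ba <- bland_altman(c(1, 2, 3), c(0.9, 2.2, 2.9))
  expect_equal(tidy(ba)$term, c("bias", "loa_lower", "loa_upper"))
  expect_equal(glance(ba)$n, 3L)
})
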