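#' Percent dilation of a vein diameter series
#'
#' The dilation statistic used to compare subjects with different resting
#' diameters: `%DV = max(series) / base * 100`, and the maximum increment is
#' `%DV - 100`. Scale-invariant: multiplying the series and the baseline by
#' any positive constant leaves both unchanged.
#'
#' @param vd_series Numeric vector of post-stimulus diameters (mm), nonempty.
#' @param vd_base Baseline (pre-stimulus) diameter (mm), > 0.
#' @return A one-row tibble: `percent_dv`, `increment_pct`.
#' @export
#' @examples
#' percent_dv(c(3.19, 2.88, 2.58, 2.5, 2.37), vd_base = 2.29)
percent_dv <- function(vd_series, vd_base) {
  if (length(vd_series) == 0L) abort("`vd_series` must be nonempty.")
  if (!is.numeric(vd_base) || vd_base <= 0) abort("`vd_base` must be positive.")
  pdv <- max(vd_series) / vd_base * 100
  tibble::tibble(percent_dv = pdv, increment_pct = pdv - 100)
}

#' Fit a negative-exponential decay
#'
#' Both the vein diameter and the skin temperature relax toward baseline
#' after the thermal stimulus is removed; the model is
#' `y(t) = c + a * exp(-t / tau)` with an offset `c` (skin temperature does
#' not decay to zero). Fitted by Levenberg-Marquardt nonlinear least squares
#' with the deterministic initialization `c0 = min(y)`, `a0 = y[1] - c0`,
#' `tau0 = range(t) / 2`, plus a bounded set of jittered-tau restarts if the
#' first attempt fails to converge.
#'
#' A constant series is degenerate (`SStot = 0`): it is reported with
#' `a = 0`, `r_squared = NA` and `degenerate = TRUE`, not as an error.
#'
#' @param t Time points in minutes, strictly increasing, >= 4 of them.
#' @param y Observed values at `t`.
#' @param max_restarts Additional jittered starts tried on non-convergence.
#' @return An object of class `decay_fit` with elements `a`, `tau`, `c`,
#'   `r_squared`, `fitted`, `residuals`, `data`, `degenerate`.
#' @export
fit_decay <- function(t, y, max_restarts = 5) {
  if (length(t) != length(y)) abort("`t` and `y` must match in length.")
  if (length(t) < 4L) abort("Need at least 4 points to fit a 3-parameter decay.")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  dat <- tibble::tibble(t = t, y = y)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    return(structure(
      list(
        a = 0, tau = NA_real_, c = y[1], r_squared = NA_real_,
        fitted = y, residuals = rep(0, length(y)), data = dat,
        degenerate = TRUE
      ),
      class = "decay_fit"
    ))
  }
  c0 <- min(y)
  a0 <- y[1] - c0
  if (a0 == 0) a0 <- diff(range(y))
  tau0 <- diff(range(t)) / 2
  starts <- c(tau0, tau0 * 2^seq_len(max_restarts) * c(1, -1)[1 + seq_len(max_restarts) %% 2])
  starts <- abs(starts)
  fit <- NULL
  last_err <- NULL
  for (tau_start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c + a * exp(-t / tau),
        data = dat,
        start = list(a = a0, tau = tau_start, c = c0),
        lower = c(-Inf, 1e-8, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(sprintf("Exponential decay fit did not converge (last error: %s).", last_err))
  }
  cf <- coef(fit)
  fitted <- cf["c"] + cf["a"] * exp(-t / cf["tau"])
  resid <- y - fitted
  structure(
    list(
      a = unname(cf["a"]), tau = unname(cf["tau"]), c = unname(cf["c"]),
      r_squared = 1 - sum(resid^2) / sstot,
      fitted = fitted, residuals = resid, data = dat, degenerate = FALSE
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<decay_fit> degenerate (constant series); a = 0\n")
  } else {
    cat(sprintf(
      "<decay_fit> y(t) = %.4g + %.4g * exp(-t / %.4g), R^2 = %.4f\n",
      x$c, x$a, x$tau, x$r_squared
    ))
  }
  invisible(x)
}

#' Linear correlation between skin temperature and vein diameter
#'
#' Ordinary least squares of diameter on skin temperature, with R-squared as
#' the squared Pearson correlation; quantifies the proportionality between
#' the two time courses after the stimulus.
#'
#' @param tskin Skin temperatures (deg C), length >= 3, nonzero variance.
#' @param vd Vein diameters (mm), same length.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`.
#' @export
correlate_vd_tskin <- function(tskin, vd) {
  if (length(tskin) != length(vd)) abort("Lengths differ.")
  if (length(tskin) < 3L) abort("Need at least 3 points.")
  if (sd(tskin) == 0) abort("`tskin` has zero variance; slope is undefined.")
  f <- lm(vd ~ tskin)
  cf <- coef(f)
  tibble::tibble(
    slope = unname(cf["tskin"]), intercept = unname(cf["(Intercept)"]),
    r_squared = suppressWarnings(summary(f))$r.squared # exact fits are fine
  )
}

#' Fit the final-diameter prediction model
#'
#' Multiple linear regression of the post-stimulus vein diameter at
#' `final_time` on three pre-measurable predictors: initial skin temperature,
#' initial vein diameter, and final skin temperature:
#' `VD_fin = b0 + b1 * Tskin_ini + b2 * VD_ini + b3 * Tskin_fin`.
#'
#' @param records A data frame with columns `tskin_ini_c`, `vd_ini_mm`,
#'   `tskin_fin_c` and either `vd_fin_mm` or a `series` to be indexed at
#'   `final_time` — a `vein_cohort` from [simulate_cohort()] works directly.
#' @param final_time Time (min after stimulus off) defining the response when
#'   the input carries a time series; ignored when `vd_fin_mm` is present.
#' @return An object of class `vd_model` wrapping the `lm` fit, with
#'   `coefficients` named `b0`..`b3`, `r_squared`, `sigma`, `n`, and
#'   `source = "fitted"`.
#' @export
fit_prediction_model <- function(records, final_time = 5) {
  df <- cohort_model_frame(records, final_time)
  if (nrow(df) < 5L) abort("Need at least 5 complete records to fit 4 parameters.")
  f <- lm(vd_fin_mm ~ tskin_ini_c + vd_ini_mm + tskin_fin_c, data = df)
  if (any(is.na(coef(f)))) {
    abort("Design matrix is rank deficient (collinear or constant predictors).")
  }
  sm <- suppressWarnings(summary(f)) # noise-free cohorts fit perfectly
  structure(
    list(
      coefficients = setNames(coef(f), c("b0", "b1", "b2", "b3")),
      r_squared = sm$r.squared, sigma = sm$sigma, n = nrow(df),
      fit = f, data = df, source = "fitted"
    ),
    class = "vd_model"
  )
}

# Normalize prediction-model input into a flat model frame.
cohort_model_frame <- function(records, final_time) {
  if (inherits(records, "vein_cohort")) {
    fin <- dplyr::filter(records$series, .data$t_min == final_time)
    if (nrow(fin) == 0L) {
      abort(sprintf("No series samples at final_time = %s min.", final_time))
    }
    df <- dplyr::left_join(
      dplyr::select(records$subjects, -dplyr::any_of("vd_fin_mm")),
      dplyr::select(fin, "subject_id", vd_fin_mm = "vd_mm"),
      by = "subject_id"
    )
  } else {
    df <- tibble::as_tibble(records)
  }
  need <- c("tskin_ini_c", "vd_ini_mm", "tskin_fin_c", "vd_fin_mm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  df <- df[stats::complete.cases(df[need]), ]
  df
}

#' The published prediction-model coefficients
#'
#' The reference multiple-regression coefficients for the final vein
#' diameter under the low room-temperature condition:
#' `VD_fin = -17.9 + 0.28 * Tskin_ini + 0.93 * VD_ini + 0.37 * Tskin_fin`
#' (diameters in mm, temperatures in deg C). Returned as a `vd_model` with
#' `source = "published"` so predictions record which coefficients were used.
#'
#' @return A `vd_model` with fixed coefficients and no fit diagnostics.
#' @export
vd_model_published <- function() {
  structure(
    list(
      coefficients = c(b0 = -17.9, b1 = 0.28, b2 = 0.93, b3 = 0.37),
      r_squared = NA_real_, sigma = NA_real_, n = NA_integer_,
      fit = NULL, data = NULL, source = "published"
    ),
    class = "vd_model"
  )
}

#' @export
print.vd_model <- function(x, ...) {
  b <- x$coefficients
  cat(sprintf(
    "<vd_model [%s]> VD_fin = %.3g + %.3g*Tskin_ini + %.3g*VD_ini + %.3g*Tskin_fin\n",
    x$source, b[1], b[2], b[3], b[4]
  ))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f, residual sd = %.3f mm, n = %d\n", x$r_squared, x$sigma, x$n))
  }
  invisible(x)
}

#' Predict the final vein diameter
#'
#' @param model A `vd_model` ([fit_prediction_model()] or
#'   [vd_model_published()]), or a numeric vector `c(b0, b1, b2, b3)`.
#' @param tskin_ini Initial skin temperature, deg C.
#' @param vd_ini Initial vein diameter, mm.
#' @param tskin_fin Final skin temperature, deg C.
#' @return A tibble with `vd_pred_mm` and `model_source`, one row per input.
#' @export
#' @examples
#' predict_vd(vd_model_published(), tskin_ini = 33, vd_ini = 2.3, tskin_fin = 36)
predict_vd <- function(model, tskin_ini, vd_ini, tskin_fin) {
  if (inherits(model, "vd_model")) {
    b <- model$coefficients
    src <- model$source
  } else {
    b <- as.numeric(model)
    src <- "coefficients"
  }
  if (length(b) != 4L || any(!is.finite(b))) {
    abort("A prediction model has four finite coefficients (b0..b3).")
  }
  b <- unname(b)
  tibble::tibble(
    vd_pred_mm = b[1] + b[2] * tskin_ini + b[3] * vd_ini + b[4] * tskin_fin,
    model_source = src
  )
}

#' Bland-Altman agreement between measured and predicted diameters
#'
#' Differences are `measured - predicted`; the bias is their mean and the
#' limits of agreement are `bias +/- 1.96 * sd` with the sample (n-1)
#' standard deviation. For normally distributed differences the limits
#' contain about 95% of pairs.
#'
#' @param measured,predicted Numeric vectors (mm), equal length >= 2.
#' @return An object of class `bland_altman` with `bias`, `loa_lower`,
#'   `loa_upper`, `sd_diff`, `n`, and `data` (tibble of per-pair `mean` and
#'   `diff`).
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted)) abort("Lengths differ.")
  if (length(measured) < 2L) abort("Need at least 2 pairs.")
  d <- measured - predicted
  m <- (measured + predicted) / 2
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(
      bias = bias, sd_diff = s,
      loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
      n = length(d), data = tibble::tibble(mean = m, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.4f, limits of agreement [%.4f, %.4f] (n = %d)\n",
    x$bias, x$loa_lower, x$loa_upper, x$n
  ))
  invisible(x)
}

#' Paired two-tailed Student's t-test
#'
#' Before/after comparison on paired measurements. When every difference is
#' exactly zero the test statistic is undefined; by convention that case is
#' reported with `p = 1` (no evidence of change) rather than an error.
#' Nonzero constant differences still error (zero variance with a nonzero
#' mean difference).
#'
#' @param before,after Numeric vectors, equal length >= 2.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_ttest <- function(before, after) {
  if (length(before) != length(after)) abort("Lengths differ.")
  if (length(before) < 2L) abort("Need at least 2 pairs.")
  d <- after - before
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(
        t = 0, df = length(d) - 1L, p_value = 1, mean_difference = 0
      ))
    }
    abort("Zero variance of nonzero differences; t statistic undefined.")
  }
  tt <- t.test(after, before, paired = TRUE, alternative = "two.sided")
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_difference = unname(tt$estimate)
  )
}
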