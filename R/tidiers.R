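#' Tidy a decay fit
#'
#' @param x A [fit_decay()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "tau", "c"),
    estimate = c(x$a, x$tau, x$c)
  )
}

#' @rdname tidy.decay_fit
#' @return `glance`: a one-row model summary.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    sigma = if (x$degenerate) 0 else sd(x$residuals),
    n = nrow(x$data),
    degenerate = x$degenerate
  )
}

#' @rdname tidy.decay_fit
#' @param data Unused (observations are stored with the fit).
#' @return `augment`: the data with `.fitted` and `.resid`.
#' @export
augment.decay_fit <- function(x, data = NULL, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' Tidy the final-diameter prediction model
#'
#' @param x A `vd_model`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate` (plus `std.error`,
#'   `statistic`, `p.value` when the model was fitted here).
#' @export
tidy.vd_model <- function(x, ...) {
  terms <- c("(Intercept)", "tskin_ini_c", "vd_ini_mm", "tskin_fin_c")
  if (is.null(x$fit)) {
    return(tibble::tibble(term = terms, estimate = unname(x$coefficients)))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.vd_model
#' @export
glance.vd_model <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, sigma = x$sigma, n = x$n, source = x$source
  )
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return `tidy`: one row per quantity (`bias`, `loa_lower`, `loa_upper`).
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper)
  )
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    loa_half_width = 1.96 * x$sd_diff, n = x$n
  )
}

#' Plot a decay fit
#'
#' Observed points with the fitted negative-exponential curve.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200)
  )
  grid$y <- if (object$degenerate) {
    rep(object$c, nrow(grid))
  } else {
    object$c + object$a * exp(-grid$t / object$tau)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "Time after stimulus off (min)", y = "Value",
      subtitle = if (object$degenerate) {
        "degenerate (constant series)"
      } else {
        sprintf(
          "y = %.3g + %.3g exp(-t/%.3g),  R² = %.3f",
          object$c, object$a, object$tau, object$r_squared
        )
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Bland-Altman analysis
#'
#' Per-pair differences against means with the bias and the 95% limits of
#' agreement.
#'
#' @param object A `bland_altman`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_lower, object$loa_upper),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "Mean of measured and predicted (mm)",
      y = "Measured - predicted (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated cohort
#'
#' Per-subject diameter and skin-temperature time courses.
#'
#' @param object A `vein_cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vein_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("tskin_c", "vd_mm"),
    names_to = "signal", values_to = "value"
  )
  labs <- c(tskin_c = "Skin temperature (°C)", vd_mm = "Vein diameter (mm)")
  long$signal <- labs[long$signal]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t_min, y = .data$value, group = .data$subject_id
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "Time after stimulus off (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation prediction
#'
#' Probability map as a raster image.
#'
#' @param object A `mask_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mask_prediction <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$prob)), times = ncol(object$prob)),
    col = rep(seq_len(ncol(object$prob)), each = nrow(object$prob)),
    prob = as.vector(object$prob)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "P(vein)") +
    ggplot2::theme_minimal()
}

#' Plot per-region diameter time courses from a pipeline run
#'
#' @param diameters The `diameters` tibble from [run_pipeline()].
#' @return A ggplot.
#' @export
plot_diameter_series <- function(diameters) {
  ggplot2::ggplot(diameters, ggplot2::aes(
    x = .data$t_min, y = .data$mean_mm, colour = .data$region
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_mm - .data$sd_mm, ymax = .data$mean_mm + .data$sd_mm
    )) +
    ggplot2::labs(
      x = "Time (min)", y = "Mean region diameter (mm)", colour = "Region"
    ) +
    ggplot2::theme_minimal()
}
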