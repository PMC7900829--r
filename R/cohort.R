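#' Parameters for a synthetic thermal-stimulation cohort
#'
#' Describes the statistical structure a simulated cohort must have so the
#' downstream dynamics statistics are testable without subject data: baseline
#' skin temperature and vein diameter distributions, a linear generating
#' model for the final diameter
#' `VD_fin = b0 + b1 * Tskin_ini + b2 * VD_ini + b3 * Tskin_fin + noise`,
#' and negative-exponential post-stimulus relaxation of both the diameter and
#' the skin temperature toward their baselines.
#'
#' Defaults emulate the low room-temperature study condition: baseline
#' diameter 2.29 +/- 0.45 mm, the published generating coefficients
#' (-17.9, 0.28, 0.93, 0.37), diameter relaxation time constant 1.6 min
#' (matching the printed 5-min mean time course), slower skin-temperature
#' relaxation (3.5 min; skin does not return to baseline within 5 min), and
#' a 0.3 mm residual sd (consistent with +/- 0.6 mm limits of agreement).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param coef Generating coefficients `c(b0, b1, b2, b3)`.
#' @param tskin_ini_mean,tskin_ini_sd Baseline skin temperature, deg C.
#' @param vd_ini_mean,vd_ini_sd Baseline vein diameter, mm.
#' @param tskin_fin_mean,tskin_fin_sd Final skin temperature, deg C.
#' @param tau_vd,tau_tskin Relaxation time constants, min (> 0).
#' @param noise_sd Residual sd of the final diameter around the generating
#'   model, mm (>= 0).
#' @param series_noise_sd Optional measurement noise added to every series
#'   sample, mm or deg C (>= 0).
#' @param t_grid Post-stimulus sampling times, min (strictly increasing).
#' @param final_time Time point whose diameter the generating model fixes.
#' @param study Study label carried on each record.
#' @param seed Integer seed; the sole source of randomness.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 10,
                          coef = c(-17.9, 0.28, 0.93, 0.37),
                          tskin_ini_mean = 31.5, tskin_ini_sd = 1.0,
                          vd_ini_mean = 2.29, vd_ini_sd = 0.45,
                          tskin_fin_mean = 35.5, tskin_fin_sd = 1.0,
                          tau_vd = 1.6, tau_tskin = 3.5,
                          noise_sd = 0.3, series_noise_sd = 0,
                          t_grid = 1:5, final_time = 5,
                          study = "A", seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (length(coef) != 4L) abort("`coef` must be c(b0, b1, b2, b3).")
  sds <- c(tskin_ini_sd, vd_ini_sd, tskin_fin_sd, noise_sd, series_noise_sd)
  if (any(sds < 0)) abort("Standard deviations must be >= 0.")
  if (tau_vd <= 0 || tau_tskin <= 0) abort("Time constants must be positive.")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing.")
  if (!final_time %in% t_grid) abort("`final_time` must be on `t_grid`.")
  structure(as.list(environment()), class = "cohort_params")
}

#' Simulate a thermal-stimulation cohort
#'
#' Draws per-subject baselines, applies the generating linear model to the
#' final diameter, and lays down post-stimulus time courses
#' `y(t) = c + a * exp(-t / tau)` that relax toward baseline (`c` is the
#' baseline value) with the amplitude pinned so that the series passes
#' exactly through the generated final value at `final_time`. With
#' `noise_sd = 0` every subject's final diameter satisfies the generating
#' equation to machine precision, so ordinary least squares recovers the
#' coefficients exactly.
#'
#' @param params A [cohort_params()].
#' @return An object of class `vein_cohort`: a list with `subjects` (tibble:
#'   `subject_id`, `tskin_ini_c`, `vd_ini_mm`, `tskin_fin_c`, `vd_fin_mm`,
#'   `group`, `study`), `series` (tibble: `subject_id`, `t_min`, `tskin_c`,
#'   `vd_mm`), and `params`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_params(n_subjects = 6, noise_sd = 0, seed = 7))
#' fit_prediction_model(coh, final_time = 5)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_subjects
    tskin_ini <- rnorm(n, p$tskin_ini_mean, p$tskin_ini_sd)
    vd_ini <- abs(rnorm(n, p$vd_ini_mean, p$vd_ini_sd))
    tskin_fin <- rnorm(n, p$tskin_fin_mean, p$tskin_fin_sd)
    vd_fin <- p$coef[1] + p$coef[2] * tskin_ini + p$coef[3] * vd_ini +
      p$coef[4] * tskin_fin + rnorm(n, 0, p$noise_sd)
    subjects <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      tskin_ini_c = tskin_ini, vd_ini_mm = vd_ini,
      tskin_fin_c = tskin_fin, vd_fin_mm = vd_fin,
      group = rep(c("iii", "iv"), length.out = n),
      study = p$study
    )
    tf <- p$final_time
    series <- purrr::map(seq_len(n), function(i) {
      a_vd <- (vd_fin[i] - vd_ini[i]) / exp(-tf / p$tau_vd)
      a_ts <- (tskin_fin[i] - tskin_ini[i]) / exp(-tf / p$tau_tskin)
      vd_t <- vd_ini[i] + a_vd * exp(-p$t_grid / p$tau_vd)
      ts_t <- tskin_ini[i] + a_ts * exp(-p$t_grid / p$tau_tskin)
      if (p$series_noise_sd > 0) {
        keep <- p$t_grid != tf
        vd_t[keep] <- vd_t[keep] + rnorm(sum(keep), 0, p$series_noise_sd)
        ts_t[keep] <- ts_t[keep] + rnorm(sum(keep), 0, p$series_noise_sd)
      }
      tibble::tibble(
        subject_id = sprintf("S%02d", i), t_min = p$t_grid,
        tskin_c = ts_t, vd_mm = vd_t
      )
    })
    structure(
      list(
        subjects = subjects, series = dplyr::bind_rows(series),
        params = p
      ),
      class = "vein_cohort"
    )
  })
}

#' @export
print.vein_cohort <- function(x, ...) {
  cat(sprintf(
    "<vein_cohort> %d subject(s), %d series sample(s), study %s\n",
    nrow(x$subjects), nrow(x$series), x$params$study
  ))
  invisible(x)
}

#' @export
as_tibble.vein_cohort <- function(x, ...) {
  dplyr::left_join(x$series, x$subjects, by = "subject_id")
}
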