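#' Configuration for synthetic bladder-filling cohorts
#'
#' Bundles every knob of the synthetic-data generator: cohort size, covariate
#' ranges, the generating ("truth") coefficients of the linear inflow-rate
#' model, patient-level scatter, measurement noise, scan-time jitter,
#' post-void residual urine, and the planning bladder volume.
#'
#' The generating model for a patient's latent mean urinary inflow rate is
#' \deqn{v_{tot} = v_0 + k_{age} P_{age} + k_{wat} P_{wat} + k_{bmi} P_{bmi}
#'       + \epsilon,\qquad \epsilon \sim N(0, \sigma_{rate}^2),}
#' truncated below at 0.05 ml/min (a physiological floor; truncation counts
#' are recorded on the generated cohort).  Defaults reproduce the fitted
#' two-covariate population model (intercept 3.115 ml/min, age coefficient
#' -0.047 ml/min per year, water coefficient 0.007 ml/min per ml, no BMI
#' effect) over covariate ranges typical of a cervical-cancer radiotherapy
#' cohort: age 40-75 yr, water intake 60-600 ml, BMI 17.6-28.2 kg/m2.
#'
#' All times are minutes since bladder voiding; volumes are ml; rates ml/min.
#'
#' @param n_patients number of patients to generate.
#' @param age_range,water_range,bmi_range covariate (low, high) ranges, in
#'   years, ml and kg/m2 respectively.
#' @param truth_v0 generating intercept (net urinary inflow rate), ml/min.
#' @param truth_k_age generating age coefficient, ml/min per year.
#' @param truth_k_wat generating water-intake coefficient, ml/min per ml.
#' @param truth_k_bmi generating BMI coefficient, ml/min per (kg/m2).
#' @param rate_residual_sd SD of patient-level scatter around the linear
#'   rate model, ml/min.
#' @param noise_cv coefficient of variation of the multiplicative
#'   volume-measurement noise (dimensionless).
#' @param time_jitter_max half-width of uniform scan-time jitter, min.
#' @param residual_urine_range post-void residual urine (low, high), ml.
#' @param v_plan_range planning-CT bladder volume (low, high), ml.
#' @param covariate_dist `"uniform"` draws covariates uniformly over their
#'   ranges; `"truncnorm"` draws from a normal centred mid-range with SD a
#'   quarter of the range width, truncated to the range.
#' @param water_round_ml if positive, round generated water intakes to the
#'   nearest multiple (ml); creates the equal-water subgroups that the
#'   iterative population fit uses for initialization.
#' @param seed integer seed for reproducible generation, or `NULL` to use
#'   the current RNG stream.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [simulate_trajectory()]
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_patients = 25,
                          age_range = c(40, 75),
                          water_range = c(60, 600),
                          bmi_range = c(17.6, 28.2),
                          truth_v0 = 3.115,
                          truth_k_age = -0.047,
                          truth_k_wat = 0.007,
                          truth_k_bmi = 0,
                          rate_residual_sd = 0.5,
                          noise_cv = 0.05,
                          time_jitter_max = 2.18,
                          residual_urine_range = c(0, 30),
                          v_plan_range = c(150, 450),
                          covariate_dist = c("uniform", "truncnorm"),
                          water_round_ml = 0,
                          seed = NULL) {
  check_number(n_patients, "n_patients", min = 1)
  check_range(age_range, "age_range")
  check_range(water_range, "water_range")
  check_range(bmi_range, "bmi_range")
  check_range(residual_urine_range, "residual_urine_range")
  if (residual_urine_range[1] < 0) stopf("residual urine must be >= 0")
  check_range(v_plan_range, "v_plan_range")
  check_number(rate_residual_sd, "rate_residual_sd", min = 0)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(time_jitter_max, "time_jitter_max", min = 0)
  check_number(water_round_ml, "water_round_ml", min = 0)
  covariate_dist <- match.arg(covariate_dist)
  for (nm in c("truth_v0", "truth_k_age", "truth_k_wat", "truth_k_bmi"))
    check_number(get(nm), nm)
  structure(list(
    n_patients = as.integer(n_patients),
    age_range = age_range, water_range = water_range, bmi_range = bmi_range,
    truth_v0 = truth_v0, truth_k_age = truth_k_age,
    truth_k_wat = truth_k_wat, truth_k_bmi = truth_k_bmi,
    rate_residual_sd = rate_residual_sd, noise_cv = noise_cv,
    time_jitter_max = time_jitter_max,
    residual_urine_range = residual_urine_range,
    v_plan_range = v_plan_range,
    covariate_dist = covariate_dist,
    water_round_ml = water_round_ml,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d   covariates: %s\n", x$n_patients, x$covariate_dist))
  cat(sprintf("  age %g-%g yr, water %g-%g ml, BMI %g-%g kg/m2\n",
              x$age_range[1], x$age_range[2], x$water_range[1],
              x$water_range[2], x$bmi_range[1], x$bmi_range[2]))
  cat(sprintf("  truth: v0 %g, k_age %g, k_wat %g, k_bmi %g (ml/min units)\n",
              x$truth_v0, x$truth_k_age, x$truth_k_wat, x$truth_k_bmi))
  cat(sprintf("  rate scatter %g ml/min, volume noise CV %g, time jitter +/-%g min\n",
              x$rate_residual_sd, x$noise_cv, x$time_jitter_max))
  invisible(x)
}
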