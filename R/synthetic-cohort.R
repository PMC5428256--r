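# Physiological floor for the mean urinary inflow rate (ml/min); latent
# rates and model predictions are truncated here.
VTOT_FLOOR <- 0.05

# Floor on the volume-measurement uncertainty (ml) so zero-volume scans do
# not acquire infinite weight in the least-squares fits.
SIGMA_V_FLOOR <- 0.5

draw_covariate <- function(n, range, dist) {
  if (dist == "uniform") {
    stats::runif(n, range[1], range[2])
  } else {
    mu <- mean(range)
    sd <- diff(range) / 4
    x <- stats::rnorm(n, mu, sd)
    # resample out-of-range draws (truncated normal)
    bad <- which(x < range[1] | x > range[2])
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mu, sd)
      bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
    }
    x
  }
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates (age, water intake, BMI), planning bladder volumes and
#' post-void residual urine, and assigns each patient a latent true mean
#' urinary inflow rate from the linear-superposition model in the
#' configuration, plus Gaussian patient-level scatter, truncated at
#' 0.05 ml/min.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `bladder_cohort` with columns
#'   `patient_id`, `age_yr`, `water_ml`, `bmi_kgm2`, `v_plan_ml`,
#'   `true_vtot_mlmin`, `residual_ml`.  The number of truncated rate draws
#'   is recorded in attribute `n_truncated`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' cohort$true_vtot_mlmin
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("'config' must be a cohort_config object")
  with_seed(config$seed, {
    n <- config$n_patients
    age <- draw_covariate(n, config$age_range, config$covariate_dist)
    water <- draw_covariate(n, config$water_range, config$covariate_dist)
    if (config$water_round_ml > 0)
      water <- round(water / config$water_round_ml) * config$water_round_ml
    bmi <- draw_covariate(n, config$bmi_range, config$covariate_dist)
    v_plan <- stats::runif(n, config$v_plan_range[1], config$v_plan_range[2])
    residual <- stats::runif(n, config$residual_urine_range[1],
                             config$residual_urine_range[2])
    raw <- config$truth_v0 + config$truth_k_age * age +
      config$truth_k_wat * water + config$truth_k_bmi * bmi +
      stats::rnorm(n, 0, config$rate_residual_sd)
    vtot <- pmax(VTOT_FLOOR, raw)
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age_yr = age, water_ml = water, bmi_kgm2 = bmi,
      v_plan_ml = v_plan, true_vtot_mlmin = vtot, residual_ml = residual,
      stringsAsFactors = FALSE
    )
    attr(cohort, "n_truncated") <- sum(raw < VTOT_FLOOR)
    class(cohort) <- c("bladder_cohort", "data.frame")
    cohort
  })
}

#' Simulate a bladder-volume trajectory for one patient
#'
#' The true bladder volume at `t` minutes after voiding is
#' `residual + true_vtot * t`.  Recorded volumes carry multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` (floored at 0 ml);
#' recorded times carry uniform jitter of half-width `time_jitter_max`,
#' floored at 0 and kept in increasing order.
#'
#' @param patient one row of a [generate_cohort()] cohort (or any list with
#'   `true_vtot_mlmin`, `residual_ml` and `patient_id`).
#' @param scan_times strictly increasing scan times, minutes since voiding.
#' @param config a [cohort_config()] supplying `noise_cv` and
#'   `time_jitter_max`.
#' @return a `data.frame` with columns `patient_id`, `t_min`, `volume_ml`,
#'   `sigma_v_ml` (the scan's true measurement uncertainty,
#'   `noise_cv * true volume`, floored at 0.5 ml — the per-scan precision a
#'   calibrated scanner would report), `sigma_t_min` (the jitter
#'   half-width).
#' @examples
#' cfg <- cohort_config(n_patients = 1, noise_cv = 0, time_jitter_max = 0,
#'                      seed = 7)
#' pat <- generate_cohort(cfg)[1, ]
#' simulate_trajectory(pat, seq(0, 60, 10), cfg)
#' @export
simulate_trajectory <- function(patient, scan_times, config) {
  if (length(scan_times) < 1L || any(scan_times < 0))
    stopf("scan_times must be non-negative")
  if (is.unsorted(scan_times, strictly = TRUE))
    stopf("scan_times must be strictly increasing")
  vtot <- patient$true_vtot_mlmin
  residual <- patient$residual_ml
  true_vol <- residual + vtot * scan_times
  vol <- pmax(0, true_vol * (1 + stats::rnorm(length(scan_times), 0, config$noise_cv)))
  t_rec <- pmax(0, scan_times +
                  stats::runif(length(scan_times), -config$time_jitter_max,
                               config$time_jitter_max))
  t_rec <- sort(t_rec) # jitter never reorders scans
  data.frame(
    patient_id = rep(patient$patient_id, length(scan_times)),
    t_min = t_rec,
    volume_ml = vol,
    sigma_v_ml = pmax(config$noise_cv * true_vol, SIGMA_V_FLOOR),
    sigma_t_min = rep(config$time_jitter_max, length(scan_times)),
    stringsAsFactors = FALSE
  )
}

#' Simulate trajectories for every patient in a cohort
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param scan_times shared scan schedule, minutes since voiding
#'   (default: 7 scans at 10-min spacing).
#' @param config the [cohort_config()] used to generate the cohort.
#' @param seed optional seed for the measurement-noise stream.
#' @return a single `data.frame` stacking one trajectory per patient.
#' @export
simulate_cohort_trajectories <- function(cohort, scan_times = seq(0, 60, by = 10),
                                         config, seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cohort)), function(i)
      simulate_trajectory(cohort[i, ], scan_times, config))
    do.call(rbind, out)
  })
}

#' Read and write cohort and trajectory tables
#'
#' Plain-CSV round-trip I/O.  Cohort files carry the documented header
#' `patient_id,age_yr,water_ml,bmi_kgm2,v_plan_ml,true_vtot_mlmin,residual_ml`
#' (the latent columns are optional on read); trajectory files carry
#' `patient_id,t_min,volume_ml,sigma_v_ml,sigma_t_min` (sigmas optional).
#'
#' @param cohort,trajectories the tables to write.
#' @param path file path.
#' @return the read functions return the table; write functions return the
#'   path invisibly.
#' @name cohort_io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "age_yr", "water_ml", "bmi_kgm2",
                      "v_plan_ml"), sprintf("cohort file '%s'", path))
  num <- setdiff(names(df), "patient_id")
  for (cl in num) {
    if (!is.numeric(df[[cl]]) && nrow(df) > 0L)
      stopf("cohort file '%s': column '%s' is not numeric", path, cl)
  }
  class(df) <- c("bladder_cohort", "data.frame")
  df
}

#' @rdname cohort_io
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(as.data.frame(trajectories), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "t_min", "volume_ml"),
                sprintf("trajectory file '%s'", path))
  for (cl in setdiff(names(df), "patient_id")) {
    if (!is.numeric(df[[cl]]) && nrow(df) > 0L)
      stopf("trajectory file '%s': column '%s' is not numeric", path, cl)
  }
  df
}
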