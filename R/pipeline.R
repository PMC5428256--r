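# End-to-end pipeline: generate -> estimate -> fit -> validate -> schedule,
# with one master seed feeding named sub-streams so any stage can be re-run
# without perturbing the others.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] for the model (training) cohort; the
#'   independent test cohort reuses it with its own sub-seed.
#' @param schedule a [schedule_config()].
#' @param fit_method population-fit method: `"regression2"` (age + water),
#'   `"regression3"` (+ BMI), or `"iterative"`.
#' @param rel_dev_tolerance validation consistency tolerance (default 0.42).
#' @param scan_times shared scan schedule for simulated trajectories,
#'   minutes since voiding.
#' @param n_test_patients size of the independent validation cohort.
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            schedule = schedule_config(),
                            fit_method = c("regression2", "regression3",
                                           "iterative"),
                            rel_dev_tolerance = 0.42,
                            scan_times = seq(0, 60, by = 10),
                            n_test_patients = 24,
                            seed = 1) {
  fit_method <- match.arg(fit_method)
  if (!inherits(cohort, "cohort_config")) stopf("'cohort' must be a cohort_config")
  if (!inherits(schedule, "schedule_config"))
    stopf("'schedule' must be a schedule_config")
  check_number(rel_dev_tolerance, "rel_dev_tolerance", min = 1e-9)
  check_number(n_test_patients, "n_test_patients", min = 1)
  structure(list(cohort = cohort, schedule = schedule,
                 fit_method = fit_method,
                 rel_dev_tolerance = rel_dev_tolerance,
                 scan_times = scan_times,
                 n_test_patients = as.integer(n_test_patients),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write or read a pipeline configuration (YAML or JSON)
#'
#' `init_pipeline_config()` writes the full default configuration, the
#' starting point for editing ("config init").
#'
#' @param config a [pipeline_config()].
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @name pipeline_config_io
#' @return the path (write) or the reconstructed `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- list(cohort = unclass(config$cohort),
            schedule = unclass(config$schedule),
            fit_method = config$fit_method,
            rel_dev_tolerance = config$rel_dev_tolerance,
            scan_times = config$scan_times,
            n_test_patients = config$n_test_patients,
            seed = config$seed)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$cohort
  cohort <- cohort_config(
    n_patients = co$n_patients, age_range = as.numeric(co$age_range),
    water_range = as.numeric(co$water_range),
    bmi_range = as.numeric(co$bmi_range),
    truth_v0 = co$truth_v0, truth_k_age = co$truth_k_age,
    truth_k_wat = co$truth_k_wat, truth_k_bmi = co$truth_k_bmi,
    rate_residual_sd = co$rate_residual_sd, noise_cv = co$noise_cv,
    time_jitter_max = co$time_jitter_max,
    residual_urine_range = as.numeric(co$residual_urine_range),
    v_plan_range = as.numeric(co$v_plan_range),
    covariate_dist = co$covariate_dist, water_round_ml = co$water_round_ml,
    seed = co$seed)
  sc <- x$schedule
  schedule <- schedule_config(
    bv_tolerance_frac = sc$bv_tolerance_frac,
    rescan_interval_min = sc$rescan_interval_min, max_scans = sc$max_scans,
    restart_on_overfull = sc$restart_on_overfull,
    scan_duration_min = sc$scan_duration_min)
  pipeline_config(cohort = cohort, schedule = schedule,
                  fit_method = x$fit_method,
                  rel_dev_tolerance = x$rel_dev_tolerance,
                  scan_times = as.numeric(x$scan_times),
                  n_test_patients = x$n_test_patients, seed = x$seed)
}

#' @rdname pipeline_config_io
#' @export
init_pipeline_config <- function(path) {
  write_pipeline_config(pipeline_config(), path)
}

#' Run the full bladder-filling analysis pipeline
#'
#' Sequences the stages: generate a model cohort and its trajectories,
#' estimate per-patient inflow rates, fit the population model, validate it
#' on an independently generated test cohort, and simulate the model-guided
#' scan schedule for the test cohort.  Writes every table plus a markdown
#' report; identical configuration and seed give identical output bundles.
#'
#' @param config a [pipeline_config()].
#' @param output_dir writable directory for the bundle.
#' @return (invisibly) a list with the cohorts, fit records, `model`,
#'   `validation`, `schedule` summary and the written file paths.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  ccfg <- config$cohort
  noise_cv <- ccfg$noise_cv

  # stage 1: model cohort + trajectories
  ccfg$seed <- derive_seed(seed, 101)
  cohort <- generate_cohort(ccfg)
  traj <- simulate_cohort_trajectories(cohort, config$scan_times, ccfg,
                                       seed = derive_seed(seed, 202))

  # stage 2: per-patient rate estimates
  records <- estimate_cohort_rates(cohort, traj, noise_cv = noise_cv)

  # stage 3: population model
  model <- switch(config$fit_method,
    regression2 = fit_regression(records, include_bmi = FALSE),
    regression3 = fit_regression(records, include_bmi = TRUE),
    iterative = iterative_fit(records))

  # stage 4: validation on an independent test cohort
  tcfg <- ccfg
  tcfg$n_patients <- config$n_test_patients
  tcfg$seed <- derive_seed(seed, 303)
  test_cohort <- generate_cohort(tcfg)
  test_traj <- simulate_cohort_trajectories(test_cohort, config$scan_times,
                                            tcfg, seed = derive_seed(seed, 404))
  test_records <- estimate_cohort_rates(test_cohort, test_traj,
                                        noise_cv = noise_cv)
  validation <- validate_model(test_records, model,
                               tolerance = config$rel_dev_tolerance)

  # stage 5: model-guided scheduling over the test cohort
  schedule <- simulate_cohort_schedule(test_cohort, model, config$schedule,
                                       noise_cv = noise_cv,
                                       seed = derive_seed(seed, 505))

  paths <- list(
    cohort = file.path(output_dir, "cohort.csv"),
    trajectories = file.path(output_dir, "trajectories.csv"),
    fits = file.path(output_dir, "fits.json"),
    model = file.path(output_dir, "model.json"),
    validation = file.path(output_dir, "validation.csv"),
    schedule = file.path(output_dir, "schedule.csv"),
    report = file.path(output_dir, "report.md"))
  write_cohort(cohort, paths$cohort)
  write_trajectories(traj, paths$trajectories)
  write_fits_json(records, paths$fits)
  write_model_json(model, paths$model)
  utils::write.csv(validation$records, paths$validation, row.names = FALSE)
  utils::write.csv(schedule$sessions, paths$schedule, row.names = FALSE)
  writeLines(pipeline_report(config, model, validation, schedule),
             paths$report)

  invisible(list(cohort = cohort, trajectories = traj, records = records,
                 model = model, test_cohort = test_cohort,
                 test_records = test_records, validation = validation,
                 schedule = schedule, paths = paths))
}

# Assemble the markdown report; every number also lives in a bundle file.
pipeline_report <- function(config, model, validation, schedule) {
  vs <- validation$summary
  num <- function(x) formatC(x, format = "g", digits = 6)
  c(
    "# Bladder-filling pipeline report",
    "",
    sprintf("Master seed: %d; fit method: %s.", config$seed, config$fit_method),
    "",
    "## Population inflow-rate model (ml/min units)",
    "",
    "| coefficient | estimate | SE |",
    "|---|---|---|",
    sprintf("| v0 | %s | %s |", num(model$v0), num(model$se_v0)),
    sprintf("| k_age | %s | %s |", num(model$k_age), num(model$se_k_age)),
    sprintf("| k_wat | %s | %s |", num(model$k_wat), num(model$se_k_wat)),
    sprintf("| k_bmi | %s | %s |", num(model$k_bmi), num(model$se_k_bmi)),
    "",
    sprintf("Fitted on %d patients%s. Coefficients are identical to `model.json`.",
            model$n,
            if (!is.na(model$iterations))
              sprintf(" in %d alternation passes", model$iterations) else ""),
    "",
    "## Validation against the independent test cohort",
    "",
    sprintf("Consistent patients (|rel. dev.| <= %g): %d of %d (%.1f%%); %d nonphysical record(s) excluded.",
            config$rel_dev_tolerance, vs$n_consistent, vs$n_classified,
            vs$percent, vs$n_excluded),
    "Per-patient records: `validation.csv`.",
    "",
    "## Model-guided scan scheduling",
    "",
    sprintf("Fractions: %d. One-scan %.1f%%; within 3 scans %.1f%%; within 5 scans %.1f%%; success %.1f%%.",
            nrow(schedule$sessions), 100 * schedule$frac_one_scan,
            100 * schedule$frac_within_3, 100 * schedule$frac_within_5,
            100 * schedule$frac_success),
    sprintf("Waiting time: mean %s min, median %s min. Per-fraction table: `schedule.csv`.",
            num(schedule$mean_wait), num(schedule$median_wait))
  )
}
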