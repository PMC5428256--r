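# Model-guided pre-treatment scan scheduling: predict when the bladder
# reaches the planning volume, scan then, and on an inconsistent scan apply
# a rate correction to decide void-and-restart vs. wait-and-rescan.

#' Scheduling configuration
#'
#' @param bv_tolerance_frac fractional bladder-volume tolerance around the
#'   planning volume within which treatment proceeds (default 0.15, the
#'   +/-15% consistency band).
#' @param rescan_interval_min minimum gap between consecutive scans, min
#'   (default 10, the protocol's re-scan interval).
#' @param max_scans abort the session after this many scans (default 6).
#' @param restart_on_overfull on an overfull scan, void and restart filling
#'   with the corrected rate (default `TRUE`); when `FALSE`, treat instead
#'   if the volume is within twice the tolerance above target, else void.
#' @param scan_duration_min time one full measurement occupies, min
#'   (default 1); counted in elapsed session time, not in `wait_min`.
#' @return a `schedule_config` list.
#' @export
schedule_config <- function(bv_tolerance_frac = 0.15,
                            rescan_interval_min = 10,
                            max_scans = 6,
                            restart_on_overfull = TRUE,
                            scan_duration_min = 1) {
  if (bv_tolerance_frac <= 0 || bv_tolerance_frac >= 1)
    stopf("bv_tolerance_frac must be in (0, 1)")
  check_number(rescan_interval_min, "rescan_interval_min", min = 1e-9)
  check_number(max_scans, "max_scans", min = 1)
  check_number(scan_duration_min, "scan_duration_min", min = 0)
  structure(list(
    bv_tolerance_frac = bv_tolerance_frac,
    rescan_interval_min = rescan_interval_min,
    max_scans = as.integer(max_scans),
    restart_on_overfull = isTRUE(restart_on_overfull),
    scan_duration_min = scan_duration_min
  ), class = "schedule_config")
}

#' Predicted time of the first pre-treatment scan
#'
#' Time (minutes after voiding) at which the bladder is expected to reach
#' the planning volume, given the model-predicted inflow rate.
#'
#' @param v_plan planning bladder volume, ml.
#' @param residual post-void residual urine, ml (`v_plan > residual`).
#' @param vtot_pred predicted inflow rate, ml/min (> 0; clamp upstream).
#' @return minutes since voiding; vectorized.
#' @examples
#' predict_first_scan_time(300, 0, 3)  # 100 min
#' @export
predict_first_scan_time <- function(v_plan, residual, vtot_pred) {
  if (any(vtot_pred <= 0)) stopf("vtot_pred must be > 0")
  if (any(v_plan < residual)) stopf("v_plan must be >= residual urine")
  (v_plan - residual) / vtot_pred
}

#' Rate correction from an inconsistent scan
#'
#' Re-derives the inflow rate from the scanned volume — the filled volume
#' divided by the time since voiding — and reports the difference from the
#' previous rate as the correction factor.
#'
#' @param bv_measured scanned bladder volume, ml.
#' @param residual post-void residual urine, ml.
#' @param t minutes since voiding (> 0).
#' @param vtot_old the rate used so far, ml/min.
#' @return list with `vtot_new` (floored at 0.05 ml/min) and
#'   `factor = vtot_old - vtot_new`.
#' @examples
#' correction_factor(200, 0, 100, 2.5)  # vtot_new 2, factor 0.5
#' @export
correction_factor <- function(bv_measured, residual, t, vtot_old) {
  if (any(t <= 0)) stopf("t must be > 0")
  vtot_new <- pmax((bv_measured - residual) / t, VTOT_FLOOR)
  list(vtot_new = vtot_new, factor = vtot_old - vtot_new)
}

#' Simulate one model-guided pre-treatment session
#'
#' The patient voids at `t = 0` and the bladder refills at the latent true
#' rate; the first scan happens at the model-predicted fill time.  At each
#' scan: within the tolerance band around the planning volume, treat; above
#' it, void and restart with the scan-corrected rate (see
#' [schedule_config()]); below it, wait for the corrected-rate fill time
#' (never less than the re-scan interval, rounded up to whole minutes) and
#' rescan.  The session aborts after `max_scans` scans.
#'
#' `wait_min` accumulates all waiting after the first scan — the quantity
#' the model-guided protocol tries to drive to zero.  Scan durations count
#' toward elapsed time only.
#'
#' @param patient one cohort row (needs `v_plan_ml`, `residual_ml`,
#'   `true_vtot_mlmin`, `patient_id`).
#' @param model an `inflow_model` used for the first-scan prediction.
#' @param config a [schedule_config()].
#' @param noise_cv coefficient of variation of the per-scan volume noise.
#' @param vtot_pred optional externally supplied predicted rate, ml/min
#'   (bypasses `model`).
#' @return a `session_outcome`: `patient_id`, `n_scans`, `wait_min`,
#'   `success`, `outcome` (`"treat"` or `"abort"`), `final_bv`, and an
#'   `actions` log (`data.frame` of timestamped scan/void/wait/treat/abort
#'   steps).
#' @export
run_session <- function(patient, model = NULL, config = schedule_config(),
                        noise_cv = 0.05, vtot_pred = NULL) {
  v_plan <- patient$v_plan_ml
  if (v_plan <= 0) stopf("v_plan must be > 0")
  residual <- patient$residual_ml
  true_vtot <- patient$true_vtot_mlmin
  if (is.null(vtot_pred)) {
    if (is.null(model)) stopf("supply either 'model' or 'vtot_pred'")
    vtot_pred <- suppressWarnings(
      predict_vtot(model, patient$age_yr, patient$water_ml, patient$bmi_kgm2))
  }
  tol <- config$bv_tolerance_frac
  lo <- (1 - tol) * v_plan; hi <- (1 + tol) * v_plan

  vtot_cur <- vtot_pred
  t_clock <- predict_first_scan_time(v_plan, residual, vtot_pred)
  elapsed <- t_clock
  wait <- 0
  n_scans <- 0L
  actions <- list()
  log_action <- function(action, bv = NA_real_, rate = NA_real_) {
    actions[[length(actions) + 1L]] <<- data.frame(
      step = length(actions) + 1L, elapsed_min = elapsed, action = action,
      bv_ml = bv, vtot_mlmin = rate, stringsAsFactors = FALSE)
  }
  success <- FALSE; outcome <- "abort"; final_bv <- NA_real_

  repeat {
    n_scans <- n_scans + 1L
    bv_true <- residual + true_vtot * t_clock
    bv <- max(0, bv_true * (1 + stats::rnorm(1, 0, noise_cv)))
    elapsed <- elapsed + config$scan_duration_min
    log_action("scan", bv = bv, rate = vtot_cur)
    final_bv <- bv
    if (bv >= lo && bv <= hi) {
      success <- TRUE; outcome <- "treat"
      log_action("treat", bv = bv)
      break
    }
    if (n_scans >= config$max_scans) {
      log_action("abort", bv = bv)
      break
    }
    corr <- correction_factor(bv, residual, t_clock, vtot_cur)
    vtot_cur <- corr$vtot_new
    if (bv > hi) {
      if (!config$restart_on_overfull && bv <= (1 + 2 * tol) * v_plan) {
        # overfull but close: treat rather than reset the session
        outcome <- "treat"
        log_action("treat", bv = bv)
        break
      }
      log_action("void", bv = bv, rate = vtot_cur)
      t_clock <- predict_first_scan_time(v_plan, residual, vtot_cur)
      wait <- wait + t_clock
      elapsed <- elapsed + t_clock
    } else {
      dt <- max(ceiling((v_plan - bv) / vtot_cur), config$rescan_interval_min)
      log_action("wait", rate = vtot_cur)
      wait <- wait + dt
      elapsed <- elapsed + dt
      t_clock <- t_clock + dt
    }
  }
  structure(list(
    patient_id = patient$patient_id, n_scans = n_scans, wait_min = wait,
    success = success, outcome = outcome, final_bv = final_bv,
    vtot_pred = vtot_pred, actions = do.call(rbind, actions)
  ), class = "session_outcome")
}

#' @export
print.session_outcome <- function(x, ...) {
  cat(sprintf("Session %s: %s after %d scan(s), wait %.0f min, final BV %.0f ml\n",
              x$patient_id, x$outcome, x$n_scans, x$wait_min, x$final_bv))
  invisible(x)
}

#' Simulate scheduled sessions over a cohort
#'
#' Runs [run_session()] for every patient and repetition (one repetition per
#' treatment fraction) and summarises scan counts and waiting times:
#' fractions needing one scan, at most 3 and at most 5 scans, wait-time
#' summaries, and histogram tables (scan-count bins 1..max and 12-min wait
#' bins).
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param model an `inflow_model` for first-scan prediction.
#' @param config a [schedule_config()].
#' @param noise_cv per-scan volume noise CV.
#' @param n_reps fractions simulated per patient.
#' @param seed optional seed for the scan-noise stream.
#' @return a `schedule_summary` list: `sessions` (per-fraction table),
#'   `frac_one_scan`, `frac_within_3`, `frac_within_5`, `frac_success`,
#'   `mean_wait`, `median_wait`, `scan_hist`, `wait_hist`.
#' @export
simulate_cohort_schedule <- function(cohort, model, config = schedule_config(),
                                     noise_cv = 0.05, n_reps = 1, seed = NULL) {
  if (nrow(cohort) == 0L) stopf("empty cohort")
  with_seed(seed, {
    rows <- list()
    for (rep in seq_len(n_reps)) {
      for (i in seq_len(nrow(cohort))) {
        s <- run_session(cohort[i, ], model = model, config = config,
                         noise_cv = noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          fraction_id = sprintf("%s_f%02d", s$patient_id, rep),
          patient_id = s$patient_id, n_scans = s$n_scans,
          wait_min = s$wait_min, outcome = s$outcome, success = s$success,
          stringsAsFactors = FALSE)
      }
    }
    sessions <- do.call(rbind, rows)
    ns <- sessions$n_scans
    scan_bins <- factor(pmin(ns, config$max_scans),
                        levels = seq_len(config$max_scans))
    wait_breaks <- seq(0, max(sessions$wait_min, 12) + 12, by = 12)
    wait_bins <- cut(sessions$wait_min, breaks = wait_breaks,
                     include.lowest = TRUE, right = FALSE)
    structure(list(
      sessions = sessions,
      frac_one_scan = mean(ns == 1),
      frac_within_3 = mean(ns <= 3 & sessions$success),
      frac_within_5 = mean(ns <= 5 & sessions$success),
      frac_success = mean(sessions$success),
      mean_wait = mean(sessions$wait_min),
      median_wait = stats::median(sessions$wait_min),
      scan_hist = as.data.frame(table(scans = scan_bins)),
      wait_hist = as.data.frame(table(wait_bin = wait_bins))
    ), class = "schedule_summary")
  })
}

#' @export
print.schedule_summary <- function(x, ...) {
  cat(sprintf("Scheduled %d fractions: %.1f%% one-scan, %.1f%% within 3, %.1f%% within 5 scans\n",
              nrow(x$sessions), 100 * x$frac_one_scan, 100 * x$frac_within_3,
              100 * x$frac_within_5))
  cat(sprintf("  success %.1f%%; wait mean %.1f min, median %.1f min\n",
              100 * x$frac_success, x$mean_wait, x$median_wait))
  invisible(x)
}
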