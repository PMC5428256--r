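# Model-validation stage: compare model-predicted inflow rates with rates
# measured in an independent (test) cohort and classify patients against a
# relative-deviation tolerance.

#' Net urinary inflow rate from two early scans
#'
#' The net rate is measured before any water intake as
#' `(BV(interval) - BV(0)) / interval`, with scans taken immediately after
#' bladder voiding.  A negative result is nonphysical but is returned
#' unchanged (flagged downstream).
#'
#' @param bv_at_0 bladder volume at `t = 0`, ml.
#' @param bv_at_10 bladder volume at `t = interval`, ml.
#' @param interval scan spacing, min (default 10).
#' @return net inflow rate, ml/min; vectorized.
#' @examples
#' measure_net_rate(10, 35)  # 2.5 ml/min
#' @export
measure_net_rate <- function(bv_at_0, bv_at_10, interval = 10) {
  if (any(interval <= 0)) stopf("interval must be > 0")
  (bv_at_10 - bv_at_0) / interval
}

#' Relative deviation of a model prediction from a measurement
#'
#' `(predicted - measured) / measured` by default; the denominator can be
#' switched to the prediction.
#'
#' @param predicted model-predicted inflow rate, ml/min.
#' @param measured measured inflow rate, ml/min (must be > 0 when it is the
#'   denominator).
#' @param denominator which value normalizes the difference.
#' @return dimensionless relative deviation(s).
#' @export
relative_model_deviation <- function(predicted, measured,
                                     denominator = c("measured", "predicted")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "measured") measured else predicted
  if (any(den <= 0))
    stopf("relative deviation undefined: %s value(s) <= 0", denominator)
  (predicted - measured) / den
}

#' Build per-patient validation records
#'
#' @param patient_id identifiers.
#' @param measured,predicted measured and model-predicted inflow rates,
#'   ml/min.
#' @param tolerance consistency tolerance on `|rel_dev|` (default 0.42).
#' @param denominator passed to [relative_model_deviation()].
#' @return `data.frame` with `patient_id`, `measured_vtot`,
#'   `predicted_vtot`, `rel_dev` (`NA` for nonphysical, non-positive
#'   measurements) and `consistent`.
#' @export
validation_records <- function(patient_id, measured, predicted,
                               tolerance = 0.42,
                               denominator = c("measured", "predicted")) {
  denominator <- match.arg(denominator)
  ok <- measured > 0
  rel <- rep(NA_real_, length(measured))
  rel[ok] <- relative_model_deviation(predicted[ok], measured[ok],
                                      denominator = denominator)
  data.frame(patient_id = patient_id, measured_vtot = measured,
             predicted_vtot = predicted, rel_dev = rel,
             consistent = !is.na(rel) & abs(rel) <= tolerance,
             stringsAsFactors = FALSE)
}

#' Classify a validated cohort against the deviation tolerance
#'
#' Counts patients whose absolute relative deviation is within the
#' tolerance.  Records with nonphysical (non-positive) measured rates are
#' excluded from the denominator but reported.
#'
#' @param records table from [validation_records()] (needs `patient_id`,
#'   `rel_dev`).
#' @param tolerance consistency tolerance (default 0.42).
#' @return list with `fraction`, `percent` (1 d.p.), `n_consistent`,
#'   `n_classified`, `n_excluded`, and `discrepant_ids`.
#' @examples
#' rec <- data.frame(patient_id = 1:24,
#'                   rel_dev = c(rep(0.1, 19), rep(0.6, 5)))
#' classify_cohort(rec)$percent  # 79.2
#' @export
classify_cohort <- function(records, tolerance = 0.42) {
  check_columns(records, c("patient_id", "rel_dev"), "validation records")
  if (nrow(records) == 0L) stopf("no validation records to classify")
  if (tolerance <= 0) stopf("tolerance must be > 0")
  usable <- !is.na(records$rel_dev)
  cons <- usable & abs(records$rel_dev) <= tolerance
  n_cl <- sum(usable)
  if (n_cl == 0L) stopf("all records excluded as nonphysical")
  frac <- sum(cons) / n_cl
  list(fraction = frac, percent = round(100 * frac, 1),
       n_consistent = sum(cons), n_classified = n_cl,
       n_excluded = sum(!usable),
       discrepant_ids = records$patient_id[usable & !cons])
}

#' Derive the consistency tolerance from method deviation summaries
#'
#' Each fitting method contributes a (mean, SD) pair of its relative
#' deviations; the tolerance is the maximum over methods of `|mean| + SD`
#' (one-SD envelope around the mean deviation).  The combination rule can be
#' overridden.
#'
#' @param method_deviations `data.frame` or list of pairs with elements
#'   `mean` and `sd` (one row/element per method).
#' @param rule function `(mean, sd) -> numeric` combined per method before
#'   taking the maximum.
#' @return dimensionless tolerance.
#' @examples
#' derive_tolerance(data.frame(mean = c(0.07, -0.02), sd = c(0.34, 0.40)))
#' # 0.42
#' @export
derive_tolerance <- function(method_deviations,
                             rule = function(mean, sd) abs(mean) + sd) {
  if (is.data.frame(method_deviations)) {
    check_columns(method_deviations, c("mean", "sd"), "method deviations")
    ms <- method_deviations$mean; ss <- method_deviations$sd
  } else {
    if (length(method_deviations) == 0L) stopf("empty deviation list")
    ms <- vapply(method_deviations, function(x) x$mean %||% x[[1]], 1)
    ss <- vapply(method_deviations, function(x) x$sd %||% x[[2]], 1)
  }
  if (length(ms) == 0L) stopf("empty deviation list")
  if (any(ss < 0)) stopf("standard deviations must be >= 0")
  max(mapply(rule, ms, ss))
}

#' Validate a fitted model against an independent cohort
#'
#' Convenience stage used by the pipeline: simulates (or accepts) measured
#' per-patient rates for a test cohort, predicts rates from the model, and
#' classifies consistency.
#'
#' @param records fit-record table for the test cohort
#'   ([estimate_cohort_rates()] output: `patient_id`, `age_yr`, `water_ml`,
#'   `bmi_kgm2`, `vtot_hat`).
#' @param model an `inflow_model`.
#' @param tolerance consistency tolerance (default 0.42).
#' @return list with the per-patient `records` table
#'   ([validation_records()]) and the [classify_cohort()] `summary`.
#' @export
validate_model <- function(records, model, tolerance = 0.42) {
  check_columns(records, c("patient_id", "age_yr", "water_ml", "vtot_hat"),
                "fit records")
  bmi <- if ("bmi_kgm2" %in% names(records)) records$bmi_kgm2 else 0
  pred <- suppressWarnings(
    predict_vtot(model, records$age_yr, records$water_ml, bmi))
  recs <- validation_records(records$patient_id, records$vtot_hat, pred,
                             tolerance = tolerance)
  list(records = recs, summary = classify_cohort(recs, tolerance = tolerance))
}
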