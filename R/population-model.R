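# Population-level model of the mean urinary inflow rate:
#   vtot = v0 + k_age * age + k_wat * water (+ k_bmi * bmi)
# fitted either by ordinary multivariable regression or by an alternating
# ("iterative") decomposition of the covariate contributions.

new_inflow_model <- function(coefs, ses, ps, method, n, iterations = NA_integer_,
                             training_ranges = NULL) {
  structure(list(
    v0 = coefs[["v0"]], k_age = coefs[["k_age"]],
    k_wat = coefs[["k_wat"]], k_bmi = coefs[["k_bmi"]],
    se_v0 = ses[["v0"]], se_k_age = ses[["k_age"]],
    se_k_wat = ses[["k_wat"]], se_k_bmi = ses[["k_bmi"]],
    p_v0 = ps[["v0"]], p_k_age = ps[["k_age"]],
    p_k_wat = ps[["k_wat"]], p_k_bmi = ps[["k_bmi"]],
    method = method, n = n, iterations = iterations,
    training_ranges = training_ranges
  ), class = "inflow_model")
}

training_ranges <- function(records) {
  list(age_yr = range(records$age_yr), water_ml = range(records$water_ml),
       bmi_kgm2 = if ("bmi_kgm2" %in% names(records)) range(records$bmi_kgm2)
                  else NULL)
}

#' Fit the population inflow-rate model by multivariable regression
#'
#' Ordinary least squares of the per-patient inflow-rate estimates on age
#' and water intake, optionally including BMI.  Coefficient standard errors
#' use the unbiased residual-variance estimate; two-sided p-values come from
#' the t distribution with `n - p` degrees of freedom.
#'
#' @param records fit-record table (columns `age_yr`, `water_ml`,
#'   `vtot_hat`; `bmi_kgm2` required when `include_bmi = TRUE`), typically
#'   from [estimate_cohort_rates()].
#' @param include_bmi include the BMI covariate (three-covariate model)?
#' @return an `inflow_model` with coefficients `v0`, `k_age`, `k_wat`,
#'   `k_bmi` (zero when excluded), their SEs and p-values, `method`
#'   `"regression3"` or `"regression2"`, and the training covariate ranges.
#' @examples
#' rec <- data.frame(age_yr = c(40, 50, 60, 70), water_ml = c(100, 300, 200, 400),
#'                   bmi_kgm2 = 23)
#' rec$vtot_hat <- 3.115 - 0.047 * rec$age_yr + 0.007 * rec$water_ml
#' fit_regression(rec, include_bmi = FALSE)
#' @export
fit_regression <- function(records, include_bmi = TRUE) {
  need <- c("age_yr", "water_ml", "vtot_hat", if (include_bmi) "bmi_kgm2")
  check_columns(records, need, "fit records")
  p <- if (include_bmi) 4L else 3L
  if (nrow(records) <= p)
    stopf("need more than %d records to fit %d parameters", p, p)
  fml <- if (include_bmi) vtot_hat ~ age_yr + water_ml + bmi_kgm2
         else vtot_hat ~ age_yr + water_ml
  fit <- stats::lm(fml, data = records)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stopf("collinear design: coefficient(s) not estimable for %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  pick <- function(tab, row, col) if (row %in% rownames(tab)) tab[row, col] else 0
  coefs <- c(v0 = pick(sm, "(Intercept)", 1), k_age = pick(sm, "age_yr", 1),
             k_wat = pick(sm, "water_ml", 1), k_bmi = pick(sm, "bmi_kgm2", 1))
  ses <- c(v0 = pick(sm, "(Intercept)", 2), k_age = pick(sm, "age_yr", 2),
           k_wat = pick(sm, "water_ml", 2),
           k_bmi = if (include_bmi) pick(sm, "bmi_kgm2", 2) else NA_real_)
  ps <- c(v0 = pick(sm, "(Intercept)", 4), k_age = pick(sm, "age_yr", 4),
          k_wat = pick(sm, "water_ml", 4),
          k_bmi = if (include_bmi) pick(sm, "bmi_kgm2", 4) else NA_real_)
  new_inflow_model(coefs, ses, ps,
                   method = if (include_bmi) "regression3" else "regression2",
                   n = nrow(records), training_ranges = training_ranges(records))
}

# Simple straight-line OLS returning slope/intercept with SEs and p-values.
ols_line <- function(x, y, intercept = TRUE) {
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  sm <- summary(fit)$coefficients
  xrow <- "x"
  slope <- sm[xrow, 1]; se_slope <- sm[xrow, 2]; p_slope <- sm[xrow, 4]
  if (intercept) {
    list(slope = slope, se_slope = se_slope, p_slope = p_slope,
         intercept = sm["(Intercept)", 1], se_intercept = sm["(Intercept)", 2],
         p_intercept = sm["(Intercept)", 4])
  } else {
    list(slope = slope, se_slope = se_slope, p_slope = p_slope,
         intercept = 0, se_intercept = 0, p_intercept = NA_real_)
  }
}

# Pick the initialization subgroup for the alternating fit: the largest set
# of records sharing one water value (ties broken by wider age spread).
# Falls back to binning water to the nearest `water_bin_ml` when no water
# value repeats with at least two distinct ages.
init_subgroup <- function(records, water_bin_ml) {
  find <- function(wat) {
    groups <- split(seq_along(wat), wat)
    groups <- Filter(function(ix) length(ix) >= 2L &&
                       length(unique(records$age_yr[ix])) >= 2L, groups)
    if (length(groups) == 0L) return(NULL)
    sizes <- vapply(groups, length, 1L)
    spread <- vapply(groups, function(ix) diff(range(records$age_yr[ix])), 1)
    best <- order(-sizes, -spread)[1]
    groups[[best]]
  }
  ix <- find(records$water_ml)
  if (!is.null(ix)) return(list(idx = ix, binned = FALSE))
  binned <- round(records$water_ml / water_bin_ml) * water_bin_ml
  ix <- find(binned)
  if (!is.null(ix)) return(list(idx = ix, binned = TRUE))
  stopf(paste("no equal-water subgroup found even after binning water to the",
              "nearest %g ml; cannot initialize the iterative fit"), water_bin_ml)
}

#' Fit the population inflow-rate model by alternating decomposition
#'
#' Implements the iterative two-covariate fit (BMI effect fixed to zero):
#' \enumerate{
#'   \item Initialization: within the largest subgroup of patients sharing
#'     one water-intake value (ties broken by wider age spread; water binned
#'     to the nearest `water_bin_ml` when no exact ties exist), regress
#'     `vtot_hat` on age to obtain a starting `k_age`.
#'   \item Subtract the age contribution `k_age * age` from every patient's
#'     rate and fit the remainder against water intake — a straight line
#'     whose intercept is the new `v0` and slope the new `k_wat`.
#'   \item Subtract `v0 + k_wat * water` and fit the remainder against age,
#'     updating `k_age` (with a free intercept that is folded back into `v0`,
#'     or forced to zero via `age_fit_intercept = "zero"`).
#'   \item Repeat steps 2-3 until both `|delta k_age|` and `|delta k_wat|`
#'     fall below `conv_tol`.
#' }
#' On exit the final age-fit intercept is folded into the reported `v0`, so
#' the converged model passes through the cohort means.  Reported standard
#' errors and p-values are those of the final-pass component fits (the water
#' fit for `v0`/`k_wat`, the age fit for `k_age`) and are therefore
#' estimator-dependent.
#'
#' @param records fit-record table (columns `age_yr`, `water_ml`,
#'   `vtot_hat`); at least 2 distinct ages and 2 distinct water values.
#' @param conv_tol convergence threshold on both coefficient changes
#'   (coefficients' own units; default 0.01).
#' @param max_iter maximum alternation passes.
#' @param age_fit_intercept `"free"` (default) or `"zero"` intercept in the
#'   age-component fit.
#' @param water_bin_ml fallback water-binning width for initialization, ml.
#' @return an `inflow_model` with `method = "iterative"`, `k_bmi = 0`, and
#'   the number of alternation passes in `iterations`.
#' @export
iterative_fit <- function(records, conv_tol = 0.01, max_iter = 100,
                          age_fit_intercept = c("free", "zero"),
                          water_bin_ml = 50) {
  check_columns(records, c("age_yr", "water_ml", "vtot_hat"), "fit records")
  age_fit_intercept <- match.arg(age_fit_intercept)
  age <- records$age_yr; water <- records$water_ml; y <- records$vtot_hat
  if (length(unique(age)) < 2L)
    stopf("k_age is unidentifiable: all records share one age")
  if (length(unique(water)) < 2L)
    stopf("k_wat is unidentifiable: all records share one water intake")
  sub <- init_subgroup(records, water_bin_ml)
  k_age <- ols_line(age[sub$idx], y[sub$idx])$slope
  k_wat <- Inf
  trace <- data.frame(iter = integer(0), v0 = numeric(0), k_age = numeric(0),
                      k_wat = numeric(0))
  free_int <- age_fit_intercept == "free"
  for (iter in seq_len(max_iter)) {
    # water pass: remainder after the age contribution
    wfit <- ols_line(water, y - k_age * age)
    v0 <- wfit$intercept
    k_wat_new <- wfit$slope
    # age pass: remainder after the net + water contributions
    afit <- ols_line(age, y - v0 - k_wat_new * water, intercept = free_int)
    k_age_new <- afit$slope
    trace <- rbind(trace, data.frame(iter = iter, v0 = v0, k_age = k_age_new,
                                     k_wat = k_wat_new))
    converged <- abs(k_age_new - k_age) < conv_tol &&
      abs(k_wat_new - k_wat) < conv_tol
    k_age <- k_age_new; k_wat <- k_wat_new
    if (converged) {
      v0_out <- v0 + afit$intercept # fold the age-fit intercept into v0
      coefs <- c(v0 = v0_out, k_age = k_age, k_wat = k_wat, k_bmi = 0)
      ses <- c(v0 = wfit$se_intercept, k_age = afit$se_slope,
               k_wat = wfit$se_slope, k_bmi = NA_real_)
      ps <- c(v0 = wfit$p_intercept, k_age = afit$p_slope,
              k_wat = wfit$p_slope, k_bmi = NA_real_)
      mod <- new_inflow_model(coefs, ses, ps, method = "iterative",
                              n = nrow(records), iterations = iter,
                              training_ranges = training_ranges(records))
      attr(mod, "init_binned") <- sub$binned
      return(mod)
    }
  }
  err <- simpleError(sprintf(
    "alternating fit did not converge in %d passes (tol %g)", max_iter, conv_tol))
  err$trace <- trace
  stop(err)
}

#' Predict a patient's mean urinary inflow rate
#'
#' Linear evaluation of an [fit_regression()] / [iterative_fit()] model,
#' clamped below at the physiological floor of 0.05 ml/min.  Covariates
#' outside the model's training ranges trigger an extrapolation warning;
#' clamping triggers its own warning.
#'
#' @param model an `inflow_model`.
#' @param age age, years.
#' @param water pre-session water intake, ml.
#' @param bmi body-mass index, kg/m2 (ignored when the model has
#'   `k_bmi = 0`).
#' @return predicted rate(s), ml/min, vectorized over the covariates.
#' @examples
#' m <- manual_inflow_model(v0 = 3.115, k_age = -0.047, k_wat = 0.007)
#' predict_vtot(m, age = 55, water = 300)  # 2.630
#' @export
predict_vtot <- function(model, age, water, bmi = 0) {
  if (!inherits(model, "inflow_model")) stopf("'model' must be an inflow_model")
  tr <- model$training_ranges
  if (!is.null(tr)) {
    out_age <- any(age < tr$age_yr[1] | age > tr$age_yr[2])
    out_wat <- any(water < tr$water_ml[1] | water > tr$water_ml[2])
    if (out_age || out_wat)
      warning("covariates outside the model's training range: extrapolating")
  }
  pred <- model$v0 + model$k_age * age + model$k_wat * water + model$k_bmi * bmi
  clamped <- pred < VTOT_FLOOR
  if (any(clamped))
    warning(sprintf("%d prediction(s) clamped at the %.2f ml/min floor",
                    sum(clamped), VTOT_FLOOR))
  pmax(pred, VTOT_FLOOR)
}

#' Construct an inflow model from known coefficients
#'
#' Useful for evaluating a published coefficient set or a generating truth
#' without a fitting step.
#'
#' @param v0,k_age,k_wat,k_bmi model coefficients (ml/min units).
#' @param method label stored on the model.
#' @return an `inflow_model` with `NA` standard errors and p-values and no
#'   training-range guard.
#' @export
manual_inflow_model <- function(v0, k_age = 0, k_wat = 0, k_bmi = 0,
                                method = "manual") {
  new_inflow_model(c(v0 = v0, k_age = k_age, k_wat = k_wat, k_bmi = k_bmi),
                   ses = c(v0 = NA_real_, k_age = NA_real_, k_wat = NA_real_,
                           k_bmi = NA_real_),
                   ps = c(v0 = NA_real_, k_age = NA_real_, k_wat = NA_real_,
                          k_bmi = NA_real_),
                   method = method, n = 0L)
}

#' @export
print.inflow_model <- function(x, ...) {
  cat(sprintf("Inflow-rate model (%s, n = %d%s)\n", x$method, x$n,
              if (!is.na(x$iterations)) sprintf(", %d passes", x$iterations) else ""))
  fmt <- function(v, se) if (is.na(se)) sprintf("%.4g", v)
                         else sprintf("%.4g +/- %.2g", v, se)
  cat(sprintf("  v0    = %s ml/min\n", fmt(x$v0, x$se_v0)))
  cat(sprintf("  k_age = %s ml/min per yr\n", fmt(x$k_age, x$se_k_age)))
  cat(sprintf("  k_wat = %s ml/min per ml\n", fmt(x$k_wat, x$se_k_wat)))
  if (x$k_bmi != 0 || x$method == "regression3")
    cat(sprintf("  k_bmi = %s ml/min per kg/m2\n", fmt(x$k_bmi, x$se_k_bmi)))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p` (t transform, `n - 2` d.f.).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test
#'
#' Classical paired t statistic with `n - 1` degrees of freedom.  Identical
#' series (all differences zero) return `t = 0`, `p = 1`; a nonzero
#' zero-variance difference is degenerate and raises an error.
#'
#' @param a,b paired numeric vectors, length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  if (length(a) < 2L) stopf("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
    stopf("degenerate paired test: constant nonzero differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Read and write inflow models as JSON
#'
#' Lossless round-trip of an `inflow_model` (coefficients, SEs, p-values,
#' method, sample size, iteration count, training ranges).
#'
#' @param model an `inflow_model`.
#' @param path file path.
#' @name model_io
#' @return `write_model_json()` the path invisibly; `read_model_json()` the
#'   reconstructed `inflow_model`.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname model_io
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- x$training_ranges
  if (!is.null(tr)) tr <- lapply(tr, as.numeric)
  new_inflow_model(
    coefs = c(v0 = x$v0, k_age = x$k_age, k_wat = x$k_wat, k_bmi = x$k_bmi),
    ses = c(v0 = x$se_v0 %||% NA_real_, k_age = x$se_k_age %||% NA_real_,
            k_wat = x$se_k_wat %||% NA_real_, k_bmi = x$se_k_bmi %||% NA_real_),
    ps = c(v0 = x$p_v0 %||% NA_real_, k_age = x$p_k_age %||% NA_real_,
           k_wat = x$p_k_wat %||% NA_real_, k_bmi = x$p_k_bmi %||% NA_real_),
    method = x$method, n = x$n %||% 0L,
    iterations = x$iterations %||% NA_integer_, training_ranges = tr
  )
}
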