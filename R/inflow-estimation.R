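# Per-patient inflow-rate estimation: straight-line fits to bladder-volume
# trajectories, in the chi-square (known-uncertainty) convention: parameter
# covariance from the weighted normal equations, goodness of fit from the
# chi-square survival probability.

#' Chi-square survival probability
#'
#' Upper-tail probability `P(X > chi2)` for a chi-square variable with `ndf`
#' degrees of freedom — the fit probability reported alongside a
#' least-squares chi-square.  Equivalent to the regularized upper incomplete
#' gamma function `Q(ndf/2, chi2/2)`.
#'
#' @param chi2 chi-square statistic(s), >= 0.
#' @param ndf degrees of freedom, >= 1.
#' @return probability in `[0, 1]`, vectorized over `chi2`/`ndf`.
#' @examples
#' chi2_survival(5.647, 11)  # 0.896
#' chi2_survival(8.873, 16)  # 0.919
#' @export
chi2_survival <- function(chi2, ndf) {
  if (any(chi2 < 0)) stopf("chi2 must be >= 0")
  if (any(ndf < 1)) stopf("ndf must be >= 1")
  stats::pchisq(chi2, df = ndf, lower.tail = FALSE)
}

#' Relative bladder volume series
#'
#' Computes `dv = V(t) - V0` and the relative deviation `dv / V0`, where
#' `V0` is the volume of the first scan (`t = 0` reference).
#'
#' @param traj trajectory `data.frame` with columns `t_min`, `volume_ml`.
#' @return a `data.frame` with columns `t_min`, `dv_ml`, `rel_dv`; `rel_dv`
#'   is `NA` (with a warning) when `V0 = 0`.
#' @export
relative_volume <- function(traj) {
  check_columns(traj, c("t_min", "volume_ml"), "trajectory")
  v0 <- traj$volume_ml[1]
  dv <- traj$volume_ml - v0
  if (v0 > 0) {
    rel <- dv / v0
  } else {
    warning("V0 = 0: relative deviation undefined, returning NA ratios")
    rel <- rep(NA_real_, length(dv))
  }
  data.frame(t_min = traj$t_min, dv_ml = dv, rel_dv = rel)
}

# Closed-form weighted straight-line fit y = a + v * t with known sigmas.
# Returns estimates, their normal-equations covariance and the chi-square.
wls_line <- function(t, y, sigma) {
  w <- 1 / sigma^2
  S <- sum(w); Sx <- sum(w * t); Sy <- sum(w * y)
  Sxx <- sum(w * t^2); Sxy <- sum(w * t * y)
  delta <- S * Sxx - Sx^2
  if (!is.finite(delta) || delta <= .Machine$double.eps * S * Sxx)
    stopf("degenerate design: scan times carry no spread")
  a <- (Sxx * Sy - Sx * Sxy) / delta
  v <- (S * Sxy - Sx * Sy) / delta
  chi2 <- sum(w * (y - a - v * t)^2)
  list(intercept = a, slope = v,
       se_slope = sqrt(S / delta), se_intercept = sqrt(Sxx / delta),
       chi2 = chi2)
}

resolve_sigma_v <- function(traj, noise_cv) {
  if ("sigma_v_ml" %in% names(traj) && !anyNA(traj$sigma_v_ml) &&
      all(traj$sigma_v_ml > 0)) {
    traj$sigma_v_ml
  } else {
    pmax(noise_cv * traj$volume_ml, SIGMA_V_FLOOR)
  }
}

new_inflow_fit <- function(patient_id, fit, n, method, iterations = NA_integer_) {
  ndf <- n - 2L
  structure(list(
    patient_id = patient_id,
    vtot = fit$slope, vtot_se = fit$se_slope,
    intercept = fit$intercept,
    chi2 = fit$chi2, ndf = ndf,
    prob = chi2_survival(fit$chi2, ndf),
    method = method, n_points = n, iterations = iterations
  ), class = "inflow_fit")
}

#' Fit the mean urinary inflow rate from one trajectory
#'
#' `fit_inflow_plain()` fits the straight line `volume = a + vtot * t` by
#' weighted least squares with volume uncertainties only ("no uncertainty in
#' scanning time").  `fit_inflow_tu()` additionally propagates scan-time
#' uncertainty through an effective-variance iteration:
#' `sigma_eff^2 = sigma_v^2 + (vtot * sigma_t)^2`, re-solving the weighted
#' fit until the slope changes by less than 1e-6 ml/min (at most 50 passes).
#' With `sigma_t = 0` the two fits coincide; with `sigma_t > 0` the
#' time-uncertainty fit reports an enlarged slope SE.
#'
#' Volume uncertainties default to `noise_cv * volume` (floored at 0.5 ml)
#' when the trajectory carries no `sigma_v_ml` column; time uncertainties
#' default to `sigma_t_default` when there is no `sigma_t_min` column.
#'
#' @param traj trajectory `data.frame` (columns `t_min`, `volume_ml`,
#'   optionally `sigma_v_ml`, `sigma_t_min`, `patient_id`); at least 3 scans.
#' @param noise_cv fallback coefficient of variation for `sigma_v_ml`.
#' @param sigma_t_default fallback scan-time uncertainty (min).
#' @return an `inflow_fit`: slope `vtot` (ml/min) with `vtot_se`, intercept
#'   (ml), `chi2`, `ndf = n - 2`, fit probability `prob`, `method`,
#'   `n_points`.
#' @examples
#' traj <- data.frame(t_min = c(0, 10, 20, 30), volume_ml = 5 + 2 * c(0, 10, 20, 30),
#'                    sigma_v_ml = 4)
#' fit_inflow_plain(traj)$vtot  # exactly 2
#' @name fit_inflow
#' @export
fit_inflow_plain <- function(traj, noise_cv = 0.05) {
  check_columns(traj, c("t_min", "volume_ml"), "trajectory")
  n <- nrow(traj)
  if (n < 3L) stopf("at least 3 scans are required to fit (got %d)", n)
  sigma <- resolve_sigma_v(traj, noise_cv)
  fit <- wls_line(traj$t_min, traj$volume_ml, sigma)
  new_inflow_fit(traj$patient_id[1] %||% NA_character_, fit, n, "plain")
}

#' @rdname fit_inflow
#' @export
fit_inflow_tu <- function(traj, noise_cv = 0.05, sigma_t_default = 2.18) {
  check_columns(traj, c("t_min", "volume_ml"), "trajectory")
  n <- nrow(traj)
  if (n < 3L) stopf("at least 3 scans are required to fit (got %d)", n)
  sigma_v <- resolve_sigma_v(traj, noise_cv)
  sigma_t <- if ("sigma_t_min" %in% names(traj) && !anyNA(traj$sigma_t_min)) {
    traj$sigma_t_min
  } else {
    rep(sigma_t_default, n)
  }
  v <- wls_line(traj$t_min, traj$volume_ml, sigma_v)$slope
  fit <- NULL
  trace <- numeric(0)
  for (iter in seq_len(50L)) {
    sigma_eff <- sqrt(sigma_v^2 + (v * sigma_t)^2)
    fit <- wls_line(traj$t_min, traj$volume_ml, sigma_eff)
    trace <- c(trace, fit$slope)
    if (abs(fit$slope - v) < 1e-6) {
      return(new_inflow_fit(traj$patient_id[1] %||% NA_character_, fit, n,
                            "time_uncertainty", iterations = iter))
    }
    v <- fit$slope
  }
  err <- simpleError(sprintf(
    "effective-variance fit did not converge in 50 iterations (last slopes: %s)",
    paste(signif(utils::tail(trace, 5), 8), collapse = ", ")))
  stop(err)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.inflow_fit <- function(x, ...) {
  cat(sprintf("Inflow fit (%s): vtot = %.3f +/- %.3f ml/min\n",
              x$method, x$vtot, x$vtot_se))
  cat(sprintf("  intercept %.2f ml; chi2/ndf = %.3f/%d (prob = %.3f); n = %d\n",
              x$intercept, x$chi2, x$ndf, x$prob, x$n_points))
  invisible(x)
}

#' Residual deviation statistics of a trajectory fit
#'
#' Summarises the relative residuals `(V_i - Vhat_i) / V0` about the plain
#' weighted-line fit, and tests their Gaussianity with a chi-square
#' comparison of equal-probability binned counts against the fitted normal
#' (bin count `ceiling(sqrt(n))`, degrees of freedom `bins - 3`).
#'
#' @param traj trajectory `data.frame`, at least 4 scans with `V0 > 0`.
#' @param noise_cv fallback volume-uncertainty CV, as in [fit_inflow_plain()].
#' @return list with `mean`, `sd` of the relative residuals, `gof_chi2`,
#'   `gof_ndf` and `gof_prob` (the Gaussian goodness-of-fit probability;
#'   `NA` when fewer than 4 bins are available or the residuals are
#'   degenerate, with `degenerate = TRUE` in the latter case).
#' @export
deviation_stats <- function(traj, noise_cv = 0.05) {
  n <- nrow(traj)
  if (n < 4L) stopf("at least 4 scans are required (got %d)", n)
  v0 <- traj$volume_ml[1]
  if (v0 <= 0) stopf("V0 must be > 0 for relative deviations")
  fit <- fit_inflow_plain(traj, noise_cv = noise_cv)
  res <- (traj$volume_ml - fit$intercept - fit$vtot * traj$t_min) / v0
  m <- mean(res); s <- stats::sd(res)
  if (s == 0) {
    return(list(mean = m, sd = s, gof_chi2 = NA_real_, gof_ndf = NA_integer_,
                gof_prob = NA_real_, degenerate = TRUE))
  }
  k <- ceiling(sqrt(n))
  ndf <- k - 3L
  if (ndf < 1L) {
    return(list(mean = m, sd = s, gof_chi2 = NA_real_, gof_ndf = NA_integer_,
                gof_prob = NA_real_, degenerate = FALSE))
  }
  # equal-probability bins under the fitted Gaussian
  edges <- stats::qnorm(seq(0, 1, length.out = k + 1), mean = m, sd = s)
  obs <- table(cut(res, breaks = edges, include.lowest = TRUE))
  expd <- n / k
  chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
  list(mean = m, sd = s, gof_chi2 = chi2, gof_ndf = ndf,
       gof_prob = chi2_survival(chi2, ndf), degenerate = FALSE)
}

#' Estimate inflow rates for every patient in a trajectory table
#'
#' Convenience wrapper: splits a stacked trajectory table by `patient_id`,
#' fits each patient, and joins the cohort covariates, producing the
#' fit-record table consumed by the population-model stage.
#'
#' @param cohort a [generate_cohort()] cohort (or any table with
#'   `patient_id`, `age_yr`, `water_ml`, `bmi_kgm2`).
#' @param trajectories stacked trajectory table
#'   ([simulate_cohort_trajectories()] output or [read_trajectories()]).
#' @param method `"plain"` or `"time_uncertainty"`.
#' @param noise_cv fallback volume-uncertainty CV.
#' @return `data.frame` with columns `patient_id`, `age_yr`, `water_ml`,
#'   `bmi_kgm2`, `vtot_hat`, `vtot_se`, `chi2`, `ndf`, `prob`.
#' @export
estimate_cohort_rates <- function(cohort, trajectories,
                                  method = c("plain", "time_uncertainty"),
                                  noise_cv = 0.05) {
  method <- match.arg(method)
  check_columns(cohort, c("patient_id", "age_yr", "water_ml", "bmi_kgm2"),
                "cohort")
  fits <- lapply(split(trajectories, trajectories$patient_id), function(tr) {
    tr <- tr[order(tr$t_min), , drop = FALSE]
    f <- if (method == "plain") fit_inflow_plain(tr, noise_cv = noise_cv)
         else fit_inflow_tu(tr, noise_cv = noise_cv)
    data.frame(patient_id = f$patient_id, vtot_hat = f$vtot,
               vtot_se = f$vtot_se, chi2 = f$chi2, ndf = f$ndf,
               prob = f$prob, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  out <- merge(cohort[, c("patient_id", "age_yr", "water_ml", "bmi_kgm2")],
               fits, by = "patient_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Export per-patient fits as JSON records
#'
#' @param fits fit-record table from [estimate_cohort_rates()].
#' @param path output path.
#' @param method method label stored with each record.
#' @return the path, invisibly.
#' @export
write_fits_json <- function(fits, path, method = "plain") {
  recs <- lapply(seq_len(nrow(fits)), function(i) {
    r <- fits[i, ]
    list(patient_id = r$patient_id, method = method, vtot = r$vtot_hat,
         vtot_se = r$vtot_se, chi2 = r$chi2, ndf = r$ndf, prob = r$prob,
         n_points = r$ndf + 2L)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
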