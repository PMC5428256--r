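# Shared fixtures and independent oracles.

# Independent weighted-straight-line oracle built on stats::lm (QR path,
# unlike the package's closed-form normal equations).  lm() scales the
# parameter covariance by the residual variance; dividing its SEs by
# sigma-hat recovers the known-uncertainty (chi-square) convention.
wls_oracle <- function(t, y, sigma) {
  fit <- lm(y ~ t, weights = 1 / sigma^2)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_slope = unname(sm$coefficients["t", 2] / sm$sigma),
       chi2 = sum((residuals(fit) / sigma)^2))
}

# Independent multivariable OLS oracle via explicit normal equations.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# Deterministic noiseless records exactly on a linear rate model; the BMI
# column is scrambled so it is not collinear with age.
make_exact_records <- function(v0, k_age, k_wat, k_bmi = 0, n = 12) {
  rec <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    age_yr = seq(40, 75, length.out = n),
    water_ml = rep(c(100, 200, 300, 400), length.out = n),
    bmi_kgm2 = rep(c(21.4, 27.9, 18.3, 24.6, 19.8, 26.1), length.out = n),
    vtot_se = 0.1)
  rec$vtot_hat <- v0 + k_age * rec$age_yr + k_wat * rec$water_ml +
    k_bmi * rec$bmi_kgm2
  rec
}

# One synthetic cohort run through per-patient estimation.
make_fit_records <- function(seed, n = 200, truth = c(3.115, -0.047, 0.007),
                             water_round_ml = 0, noise_cv = 0.05,
                             rate_residual_sd = 0.5) {
  cfg <- cohort_config(n_patients = n, truth_v0 = truth[1],
                       truth_k_age = truth[2], truth_k_wat = truth[3],
                       rate_residual_sd = rate_residual_sd,
                       noise_cv = noise_cv, water_round_ml = water_round_ml,
                       seed = seed)
  cohort <- generate_cohort(cfg)
  traj <- simulate_cohort_trajectories(cohort, seq(0, 60, by = 10), cfg,
                                       seed = seed + 10000)
  estimate_cohort_rates(cohort, traj, noise_cv = noise_cv)
}
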