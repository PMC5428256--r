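test_that("relative volume series is the shifted and scaled trajectory", {
  traj <- data.frame(t_min = c(0, 10, 20), volume_ml = c(100, 120, 140))
  rv <- relative_volume(traj)
  expect_equal(rv$dv_ml, c(0, 20, 40))
  expect_equal(rv$rel_dv, c(0, 0.2, 0.4))

  const <- data.frame(t_min = c(0, 10, 20), volume_ml = rep(50, 3))
  expect_true(all(relative_volume(const)$dv_ml == 0))

  zero <- data.frame(t_min = c(0, 10), volume_ml = c(0, 10))
  expect_warning(rv0 <- relative_volume(zero), "undefined")
  expect_equal(rv0$dv_ml, c(0, 10))
  expect_true(all(is.na(rv0$rel_dv)))

  # a noiseless generated trajectory gives a ratio series linear in t
  cfg <- cohort_config(n_patients = 1, noise_cv = 0, time_jitter_max = 0,
                       residual_urine_range = c(20, 20), seed = 1)
  pat <- list(patient_id = "P001", true_vtot_mlmin = 2.5, residual_ml = 20)
  tr <- simulate_trajectory(pat, seq(0, 60, 10), cfg)
  rel <- relative_volume(tr)$rel_dv
  expect_equal(max(abs(diff(diff(rel)))), 0, tolerance = 1e-12)
})

test_that("plain weighted fit recovers an exact line with zero chi-square", {
  t <- c(0, 10, 20, 30, 40)
  traj <- data.frame(t_min = t, volume_ml = 5 + 2 * t, sigma_v_ml = 3)
  fit <- fit_inflow_plain(traj)
  expect_equal(fit$vtot, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
  expect_equal(fit$prob, 1)
  expect_equal(fit$ndf, 3L)

  # permutation of point order leaves the fit unchanged
  shuf <- traj[c(3, 1, 5, 2, 4), ]
  fit2 <- fit_inflow_plain(shuf)
  expect_equal(fit2$vtot, fit$vtot)
  expect_equal(fit2$chi2, fit$chi2)

  expect_error(fit_inflow_plain(traj[1:2, ]), "at least 3")
  degen <- data.frame(t_min = rep(10, 4), volume_ml = c(1, 2, 3, 4),
                      sigma_v_ml = 1)
  expect_error(fit_inflow_plain(degen), "degenerate")
})

test_that("weighted fit matches an independent lm-based oracle to 1e-9", {
  set.seed(71)
  for (rep in 1:5) {
    t <- sort(runif(5, 0, 60))
    sigma <- runif(5, 1, 10)
    y <- 20 + 3 * t + rnorm(5, 0, sigma)
    traj <- data.frame(t_min = t, volume_ml = y, sigma_v_ml = sigma)
    fit <- fit_inflow_plain(traj)
    orc <- wls_oracle(t, y, sigma)
    expect_equal(fit$vtot, orc$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
    expect_equal(fit$vtot_se, orc$se_slope, tolerance = 1e-9)
    expect_equal(fit$chi2, orc$chi2, tolerance = 1e-9)
  }
})

test_that("time-uncertainty fit reduces to the plain fit and enlarges the SE", {
  set.seed(81)
  t <- seq(0, 60, 10)
  y <- 30 + 3 * t + rnorm(7, 0, 5)
  traj0 <- data.frame(t_min = t, volume_ml = y, sigma_v_ml = 5, sigma_t_min = 0)
  plain <- fit_inflow_plain(traj0)
  tu0 <- fit_inflow_tu(traj0)
  expect_equal(tu0$vtot, plain$vtot, tolerance = 1e-9)
  expect_equal(tu0$vtot_se, plain$vtot_se, tolerance = 1e-9)

  # positive time uncertainty never shrinks the slope SE
  for (rep in 1:20) {
    y <- 30 + runif(1, 1, 5) * t + rnorm(7, 0, 5)
    tr <- data.frame(t_min = t, volume_ml = y, sigma_v_ml = 5,
                     sigma_t_min = runif(1, 0.5, 2.18))
    expect_gte(fit_inflow_tu(tr)$vtot_se, fit_inflow_plain(tr)$vtot_se)
  }
})

test_that("plain and time-uncertainty fits agree within one combined SE on scan-like data", {
  # 7 scans at 10-min spacing with time uncertainty up to 2.18 min, the
  # design on which the two fitting variants are expected to be consistent
  set.seed(91)
  t <- seq(0, 60, 10)
  agree <- replicate(50, {
    v <- runif(1, 1, 5)
    y <- pmax(0, (20 + v * t) * (1 + rnorm(7, 0, 0.05)))
    tr <- data.frame(t_min = t, volume_ml = y,
                     sigma_v_ml = pmax(0.05 * y, 0.5), sigma_t_min = 2.18)
    p <- fit_inflow_plain(tr); u <- fit_inflow_tu(tr)
    abs(p$vtot - u$vtot) <= sqrt(p$vtot_se^2 + u$vtot_se^2)
  })
  expect_true(all(agree))
})

test_that("chi-square survival probability matches printed values and closed forms", {
  expect_equal(chi2_survival(5.647, 11), 0.896, tolerance = 1e-3)
  expect_equal(chi2_survival(4.145, 10), 0.940, tolerance = 1e-3)
  expect_equal(chi2_survival(8.873, 16), 0.918, tolerance = 1e-3)
  # full support at chi2 = 0
  expect_equal(chi2_survival(0, c(1, 5, 20)), c(1, 1, 1))
  # closed form exp(-x/2) at 2 degrees of freedom
  x <- c(0.5, 1, 3, 7)
  expect_equal(chi2_survival(x, 2), exp(-x / 2), tolerance = 1e-12)
  # monotonically decreasing in chi2
  expect_true(all(diff(chi2_survival(seq(0, 30, 0.5), 10)) < 0))
  expect_error(chi2_survival(-1, 5), "chi2")
  expect_error(chi2_survival(1, 0), "ndf")
})

test_that("slope estimation is unbiased over many noisy trajectories", {
  cfg <- cohort_config(n_patients = 1, noise_cv = 0.05, time_jitter_max = 0,
                       seed = 1)
  set.seed(101)
  times <- seq(0, 60, 10)
  errs <- replicate(1000, {
    v <- runif(1, 1, 5)
    pat <- list(patient_id = "P001", true_vtot_mlmin = v,
                residual_ml = runif(1, 0, 30))
    tr <- simulate_trajectory(pat, times, cfg)
    fit_inflow_plain(tr)$vtot - v
  })
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * se)
})

test_that("deviation statistics flag noiseless lines and rank tail weight", {
  t <- seq(0, 60, 10)
  clean <- data.frame(t_min = t, volume_ml = 50 + 2 * t, sigma_v_ml = 2)
  ds <- deviation_stats(clean)
  expect_equal(ds$mean, 0, tolerance = 1e-12)
  expect_equal(ds$sd, 0, tolerance = 1e-12)
  expect_true(ds$degenerate)

  # Gaussian residuals: gof probabilities roughly calibrated under the null
  set.seed(111)
  tt <- seq(0, 99)
  probs <- replicate(400, {
    y <- 100 + 2 * tt + rnorm(100, 0, 5)
    deviation_stats(data.frame(t_min = tt, volume_ml = y, sigma_v_ml = 5))$gof_prob
  })
  expect_lt(abs(mean(probs < 0.05) - 0.05), 0.045)
  # heavy-tailed residuals depress the gof probability
  probs_t <- replicate(400, {
    y <- 100 + 2 * tt + 5 * rt(100, df = 2)
    deviation_stats(data.frame(t_min = tt, volume_ml = y, sigma_v_ml = 5))$gof_prob
  })
  expect_lt(median(probs_t), median(probs))
})
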