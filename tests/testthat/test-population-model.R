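test_that("regression recovers exact linear records to machine precision", {
  rec <- make_exact_records(3.115, -0.047, 0.007)
  m2 <- suppressWarnings(fit_regression(rec, include_bmi = FALSE))
  expect_equal(m2$v0, 3.115, tolerance = 1e-9)
  expect_equal(m2$k_age, -0.047, tolerance = 1e-9)
  expect_equal(m2$k_wat, 0.007, tolerance = 1e-9)
  expect_equal(m2$k_bmi, 0)
  expect_equal(m2$method, "regression2")

  # with a BMI column of exactly zero effect, the three-covariate fit
  # reproduces the two-covariate coefficients and a null k_bmi
  m3 <- suppressWarnings(fit_regression(rec, include_bmi = TRUE))
  expect_equal(m3$k_bmi, 0, tolerance = 1e-9)
  expect_equal(c(m3$v0, m3$k_age, m3$k_wat), c(m2$v0, m2$k_age, m2$k_wat),
               tolerance = 1e-8)

  expect_error(fit_regression(rec[1:3, ], include_bmi = TRUE), "records")
  col <- rec
  col$bmi_kgm2 <- col$age_yr # perfectly collinear
  expect_error(fit_regression(col, include_bmi = TRUE), "collinear")
})

test_that("regression coefficients and SEs equal a normal-equations oracle", {
  rec <- data.frame(
    patient_id = 1:6,
    age_yr = c(42, 51, 55, 60, 68, 73),
    water_ml = c(100, 250, 300, 150, 400, 500),
    bmi_kgm2 = c(19.2, 22.5, 23.1, 24.8, 26.0, 21.3),
    vtot_hat = c(2.41, 2.93, 3.10, 1.85, 3.60, 3.95))
  m <- fit_regression(rec, include_bmi = TRUE)
  X <- cbind(1, rec$age_yr, rec$water_ml, rec$bmi_kgm2)
  orc <- ols_oracle(X, rec$vtot_hat)
  expect_equal(c(m$v0, m$k_age, m$k_wat, m$k_bmi), unname(orc$beta),
               tolerance = 1e-9)
  expect_equal(c(m$se_v0, m$se_k_age, m$se_k_wat, m$se_k_bmi),
               unname(orc$se), tolerance = 1e-9)
})

test_that("a noise-only BMI covariate is declared insignificant at the nominal rate", {
  set.seed(121)
  rejected <- replicate(300, {
    rec <- data.frame(
      age_yr = runif(50, 40, 75), water_ml = runif(50, 60, 600),
      bmi_kgm2 = runif(50, 17.6, 28.2))
    rec$vtot_hat <- 3.115 - 0.047 * rec$age_yr + 0.007 * rec$water_ml +
      rnorm(50, 0, 0.5)
    fit_regression(rec, include_bmi = TRUE)$p_k_bmi < 0.05
  })
  # ~5% type-I rate; 3 binomial SEs at 300 replicates
  expect_lt(abs(mean(rejected) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("alternating fit converges to the generating coefficients on exact data", {
  rec <- make_exact_records(2.587, -0.040, 0.007)
  m <- suppressWarnings(iterative_fit(rec))
  expect_equal(m$v0, 2.587, tolerance = 0.01)
  expect_equal(m$k_age, -0.040, tolerance = 0.01)
  expect_equal(m$k_wat, 0.007, tolerance = 0.01)
  expect_equal(m$k_bmi, 0)
  expect_equal(m$method, "iterative")
  expect_true(m$iterations >= 1)

  # invariant to record order and to patient-id relabeling
  shuf <- rec[sample(nrow(rec)), ]
  shuf$patient_id <- sprintf("Q%02d", seq_len(nrow(shuf)))
  m2 <- suppressWarnings(iterative_fit(shuf))
  expect_equal(c(m2$v0, m2$k_age, m2$k_wat), c(m$v0, m$k_age, m$k_wat),
               tolerance = 1e-9)

  # degenerate designs are rejected with an informative error
  eq_age <- rec
  eq_age$age_yr <- 55
  expect_error(iterative_fit(eq_age), "unidentifiable")
  eq_wat <- rec
  eq_wat$water_ml <- 300
  expect_error(iterative_fit(eq_wat), "unidentifiable")
})

test_that("alternating fit falls back to water binning when no exact ties exist", {
  set.seed(131)
  rec <- data.frame(age_yr = runif(60, 40, 75),
                    water_ml = runif(60, 60, 600) + runif(60, 0, 1))
  rec$vtot_hat <- 2.587 - 0.040 * rec$age_yr + 0.007 * rec$water_ml +
    rnorm(60, 0, 0.3)
  m <- iterative_fit(rec)
  expect_true(attr(m, "init_binned"))
  expect_equal(m$k_age, -0.040, tolerance = 0.015)
})

test_that("regression and alternating fits agree on noisy synthetic cohorts", {
  agree_se <- logical(0); nonsig <- logical(0)
  for (s in 1:10) {
    rec <- make_fit_records(s, n = 200, truth = c(2.587, -0.040, 0.007),
                            water_round_ml = 50)
    mr <- fit_regression(rec, include_bmi = FALSE)
    mi <- iterative_fit(rec)
    comb <- sqrt(c(mr$se_v0, mr$se_k_age, mr$se_k_wat)^2 +
                 c(mi$se_v0, mi$se_k_age, mi$se_k_wat)^2)
    dif <- abs(c(mr$v0 - mi$v0, mr$k_age - mi$k_age, mr$k_wat - mi$k_wat))
    agree_se <- c(agree_se, all(dif < comb))
    p1 <- suppressWarnings(predict_vtot(mr, rec$age_yr, rec$water_ml))
    p2 <- suppressWarnings(predict_vtot(mi, rec$age_yr, rec$water_ml))
    nonsig <- c(nonsig, paired_ttest(p1, p2)$p > 0.05)
  }
  expect_true(all(agree_se))
  expect_gte(mean(nonsig), 0.9)
})

test_that("prediction evaluates the linear model with a physiological floor", {
  m <- manual_inflow_model(3.115, -0.047, 0.007)
  expect_equal(predict_vtot(m, 55, 300), 2.630, tolerance = 1e-12)
  const <- manual_inflow_model(1)
  expect_equal(predict_vtot(const, c(40, 70), c(60, 600)), c(1, 1))
  # far extrapolation clamps at 0.05 ml/min
  low <- manual_inflow_model(2.587, -0.040, 0.007)
  expect_warning(p <- predict_vtot(low, 75, 60), "clamped")
  expect_equal(p, 0.05)
  # training-range guard warns on extrapolation
  rec <- make_exact_records(3, -0.04, 0.007)
  mf <- suppressWarnings(fit_regression(rec, include_bmi = FALSE))
  expect_warning(predict_vtot(mf, 90, 300), "training range")
})

test_that("pearson correlation reproduces exact and cohort-level relationships", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x + 10)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  # on a synthetic cohort, rate rises with water and falls with age
  rec <- make_fit_records(141, n = 200)
  rw <- pearson_r(rec$vtot_hat, rec$water_ml)
  ra <- pearson_r(rec$vtot_hat, rec$age_yr)
  expect_gt(rw$r, 0.5)
  expect_lt(rw$p, 0.01)
  expect_lt(ra$r, -0.2)
  expect_lt(ra$p, 0.01)
})

test_that("paired t-test matches the closed form and calibrates under the null", {
  a <- c(5, 6, 7, 8); b <- c(4, 4, 4, 6)
  d <- a - b
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 3), tolerance = 1e-12)
  expect_equal(paired_ttest(a, a), list(t = 0, df = 3L, p = 1))
  expect_error(paired_ttest(a, a + 1), "degenerate")
  set.seed(151)
  rej <- replicate(2000, {
    x <- rnorm(20); y <- rnorm(20)
    paired_ttest(x, y)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("models round-trip through JSON losslessly", {
  rec <- make_exact_records(2.6, -0.04, 0.007, n = 10)
  rec$vtot_hat <- rec$vtot_hat + rnorm(10, 0, 0.1)
  m <- fit_regression(rec, include_bmi = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$v0, m$v0, tolerance = 1e-12)
  expect_equal(back$k_age, m$k_age, tolerance = 1e-12)
  expect_equal(back$se_k_wat, m$se_k_wat, tolerance = 1e-12)
  expect_equal(back$p_k_age, m$p_k_age, tolerance = 1e-12)
  expect_equal(back$method, m$method)
  expect_equal(back$n, m$n)
  expect_equal(back$training_ranges$age_yr, m$training_ranges$age_yr)
})
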