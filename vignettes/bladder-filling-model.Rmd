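---
title: "Modelling bladder filling for radiotherapy preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bladder filling for radiotherapy preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bladderfill)
```

## The model and its assumptions

Radiotherapy of pelvic tumours is planned on a CT with a filled bladder,
and every treatment fraction should reproduce that bladder volume (BV)
within a tolerance band (±15% by default). `bladderfill` rests on four
assumptions about how the bladder fills after voiding:

1. BV grows **linearly** in time, at a constant mean urinary inflow rate
   `v_tot` (ml/min) per patient and session;
2. `v_tot` differs between patients;
3. it is driven mainly by age, pre-session water intake and body-mass
   index;
4. those influences are linear and additive:

   `v_tot = v0 + k_age * P_age + k_wat * P_wat + k_bmi * P_bmi`,

   where `v0` is the *net* urinary inflow rate — the rate with all
   covariate contributions removed.

The BMI term is retained in the three-covariate regression so its
(negligible) effect can be tested, and dropped everywhere else.

All times in the package are **minutes since bladder voiding**: drinking
times vary between protocols, whereas voiding is a physically unambiguous
zero for the filling process. All volumes are ml and all rates ml/min;
units are embedded in column names (`age_yr`, `water_ml`, `volume_ml`, …).

## Per-patient rate estimation

A patient's `v_tot` is the slope of a straight line fitted to their scan
series `(t_i, V_i)` by weighted least squares with *known* per-point
uncertainties — the chi-square convention used with instrument-calibrated
data. Parameter covariance comes directly from the weighted normal
equations (it is **not** rescaled by the residual variance), the minimised
sum is reported as `chi2` with `ndf = n − 2`, and the fit quality is the
survival probability `P(X > chi2)` of a chi-square variable
(`chi2_survival()`, the regularized upper incomplete gamma function).
A probability near 1 indicates an excellent (possibly over-fitted) line;
near 0, a poor one.

Two variants reflect two readings of the scan times:

* `fit_inflow_plain()` — scan times exact, only volume uncertainties enter;
* `fit_inflow_tu()` — scan times uncertain by `sigma_t` (multi-scan
  sessions smear the effective measurement time). Time uncertainty is
  folded into an **effective variance**
  `sigma_eff² = sigma_v² + (v_tot · sigma_t)²`, and the weighted fit is
  iterated (the weights depend on the slope) until the slope moves by less
  than 1e−6 ml/min, at most 50 passes. This is the standard chi-square
  treatment of errors in the abscissa for a straight line; it leaves the
  slope essentially unchanged and enlarges its standard error, so the two
  variants agree within one combined standard deviation on scan-like data —
  the behaviour the estimator is designed to reproduce.

Defaults when a trajectory carries no uncertainty columns: `sigma_v =
noise_cv × volume` floored at 0.5 ml (the floor keeps near-empty scans
from acquiring unbounded weight), and `sigma_t` equal to the configured
jitter half-width. The synthetic generator, which knows each scan's true
volume, reports `sigma_v = noise_cv × true volume` — the per-scan precision
a calibrated scanner quotes — so that fitted slopes are unbiased (weights
derived from the *measured* volume correlate with the noise and would bias
the slope by order `noise_cv²`).

The intercept is left free rather than pinned to the post-void residual
volume: the first scan of a session is itself noisy, and a free intercept
absorbs any offset without biasing the slope.

`deviation_stats()` summarises the relative residuals `(V_i − V̂_i)/V_0`
and tests their Gaussianity by comparing equal-probability binned counts
with the fitted normal; the bin count is `⌈√n⌉` (a standard rule the data
do not otherwise fix) and the chi-square uses `bins − 3` degrees of freedom
(two estimated moments). With fewer than 4 bins the test is not defined
and `NA` is returned.

## Population fitting: regression and the alternating fit

`fit_regression()` is ordinary least squares of the per-patient rate
estimates on the covariates (`stats::lm`), with classical t-based
standard errors and p-values. The per-patient estimates enter unweighted:
their uncertainties are near-identical by design (common scan schedule),
and the dominant error is patient-level scatter, not fit error.

`iterative_fit()` implements the alternating decomposition:

1. **Initialization** — among patients sharing one water-intake value, the
   regression of `v_tot` on age gives a starting `k_age`. The implemented
   rule is "largest equal-water subgroup, ties broken by wider age spread";
   when no exact ties exist, water is binned to the nearest 50 ml (a
   documented fallback, flagged on the result).
2. **Water pass** — subtract `k_age · age`; the remainder against water
   gives a new `v0` (intercept) and `k_wat` (slope).
3. **Age pass** — subtract `v0 + k_wat · water`; the remainder against age
   updates `k_age`.
4. Alternate until both coefficient changes fall below `conv_tol = 0.01`
   (the coefficients' own units).

The age pass is fitted with a **free intercept** that is folded back into
`v0` (an `age_fit_intercept = "zero"` switch forces it through the
origin). Folding is applied on exit as well, so the converged model passes
exactly through the cohort means — the same anchoring ordinary regression
has. This matters for comparing the two methods: with mean-anchoring, the
paired difference of their per-patient predictions is centred at zero and
the paired t-test measures only the (small) residual disagreement of the
coefficient estimates. On cohorts with roughly independent covariates the
alternation is a Gauss–Seidel sweep of the regression normal equations and
converges geometrically, typically in 2–3 passes.

Standard errors for the iterative method are taken from the final-pass
component fits (water fit for `v0` and `k_wat`, age fit for `k_age`).
This estimator ignores the cross-covariate uncertainty a joint fit would
carry; the method label on the model records that the SEs are
estimator-dependent and not interchangeable with regression SEs.

Both fitting routes refuse degenerate designs (all ages equal, all water
equal, collinear covariates) with errors naming the offending covariate.

## Prediction, validation, and the 0.42 tolerance

`predict_vtot()` evaluates the linear model, warns outside the training
covariate ranges, and clamps predictions below at **0.05 ml/min** — a
physiological floor (an adult kidney pair essentially never produces less)
that also keeps downstream fill-time predictions finite. The same floor
truncates generated latent rates and scan-derived rate corrections.

Validation against an independent cohort compares the model prediction
with the measured rate via the relative deviation
`(predicted − measured)/measured`; the measured value is the physical
reference, hence the denominator (a switch selects the alternative).
Patients are *consistent* when `|rel_dev| ≤ 0.42`. The 0.42 derives from
the method deviation summaries — mean ± SD of the relative deviations of
the two fitting methods (0.07 ± 0.34 and −0.02 ± 0.40) — combined as the
maximum over methods of `|mean| + SD`, a one-SD envelope. The combination
rule is explicit (`derive_tolerance()`) and overridable, since other
readings (e.g. a two-SD envelope) are defensible. Nonphysical negative
measured rates are excluded from the consistency denominator but counted
and reported.

## The scan scheduler

`run_session()` simulates one pre-treatment session:

* the first scan happens at the predicted fill time
  `(v_plan − residual)/v_tot_pred`;
* a scan within ±15% of the planning volume → **treat**;
* an *underfull* scan → re-derive the rate from the scan itself
  (`correction_factor()`: filled volume over elapsed time, floored at
  0.05 ml/min), **wait** for the corrected fill time — never less than the
  10-min re-scan interval, rounded up to whole minutes — and rescan;
* an *overfull* scan → **void and restart** the clock with the corrected
  rate. Whether to void or to wait on an inconsistent scan is a genuine
  protocol choice; voiding is the default because an overfull bladder only
  grows more overfull, and a switch (`restart_on_overfull = FALSE`)
  instead treats when the volume is within twice the tolerance above
  target, for sensitivity analysis;
* the session aborts after `max_scans` (6 by default) scans.

Each measurement occupies 1 min of elapsed time (`scan_duration_min`) but
does not count as waiting; `wait_min` accumulates all waiting after the
first scan, i.e. the time the model failed to predict away. A perfectly
predicted noiseless session therefore has one scan and zero wait, which is
also the package's degenerate-case test.

`simulate_cohort_schedule()` repeats sessions over a cohort and reports
one-scan / within-3 / within-5 fractions, wait summaries, and histogram
tables (scan-count bins and 12-min wait bins).

## What the synthetic generator emulates — and what it does not

Defaults were chosen once, as a realistic cervical-radiotherapy cohort:

* covariates uniform over age 40–75 yr, water 60–600 ml, BMI
  17.6–28.2 kg/m² — the reported ranges of such cohorts. Only mean,
  median and range are typically published, not a distribution; uniform is
  the least-committal choice and a truncated-normal alternative
  (`covariate_dist = "truncnorm"`) is exposed;
* generating coefficients default to the fitted two-covariate model
  (3.115, −0.047, 0.007);
* patient-level rate scatter `rate_residual_sd = 0.5` ml/min, which makes
  simulated cohorts span roughly the observed 0.19–5.13 ml/min range under
  the default coefficients;
* multiplicative volume noise `noise_cv = 0.05`: portable bladder scanners
  are quoted at a few percent relative error and no per-device value is
  published, so 5% is a documented assumption, config-exposed;
* scan-time jitter uniform within ±2.18 min, the maximum timing
  uncertainty of multi-scan sessions;
* post-void residual urine U(0, 30) ml (residual urine is evaluated
  clinically but values are rarely published; 30 ml is a common
  no-concern threshold);
* planning volumes U(150, 450) ml, the range in which full-bladder
  protocols typically operate.

The generator does **not** emulate: compliance drift or the systematic BV
decrease over a multi-week treatment course, diurnal or
diuretic/caffeine effects, operator-dependent measurement bias, or
intra-fraction bladder motion. Passing tests therefore demonstrate that
the estimators recover the model that generated the data at realistic
noise — parameter-recovery validity — not that real cohorts obey the
linear model; that evidence must come from measured trajectories, which
the same functions accept via `read_trajectories()`.

## Numerical choices and reproducibility

* Floors: latent and corrected rates at 0.05 ml/min; volume uncertainty at
  0.5 ml; recorded volumes and times at 0.
* Jittered scan times are kept in increasing order (with ±2.18 min jitter
  on a 10-min grid, reordering cannot occur anyway).
* Convergence: 0.01 (absolute, per coefficient) for the alternating fit;
  1e−6 ml/min for the effective-variance slope; both with iteration caps
  and informative errors carrying a coefficient trace.
* Every stochastic stage takes a seed; `run_pipeline()` derives a named
  sub-seed per stage from one master seed, so a stage can be re-run
  without perturbing the others, and identical configuration + seed gives
  a byte-identical output bundle.

The test suite exercises recovery at cohorts of 200 patients × 20 seeds
(regression and alternating fits), 1000 trajectories for slope
unbiasedness, and 10⁶ Monte-Carlo draws for the chi-square tail — sizes at
which the stochastic checks are stable at the asserted tolerances while
the whole suite stays fast.

## Known limitations

* A single `v_tot` per patient: no session-to-session rate variation
  within a patient, no mixed-effects extension.
* The iterative-method SEs are per-pass component-fit SEs (see above).
* The scheduler models one patient at a time — no appointment queueing or
  scanner-room contention.
* No robust/outlier-resistant trajectory fitting; a grossly failed scan
  should be removed before fitting.
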