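# bladderfill

Pelvic radiotherapy — cervical cancer in particular — is delivered with a
comfortably full bladder, and each treatment fraction proceeds only when the
bladder volume (BV) matches the planning-CT volume within a tolerance band
(±15% by default). In practice patients are scanned with a portable
ultrasound device at 10-minute intervals until the volume is right, which
costs scanner time, technician labour, and patient comfort.

`bladderfill` implements a parameterized model of bladder filling that turns
this guess-and-rescan loop into a prediction problem, for medical physicists
and biostatisticians studying image-guided radiotherapy preparation
workflows.

## The model

Bladder volume grows linearly after voiding, at a patient-specific **mean
urinary inflow rate** `v_tot` (ml/min):

    V(t) = V_residual + v_tot * t

`v_tot` is decomposed as a linear superposition of covariate effects,

    v_tot = v0 + k_age * P_age + k_wat * P_wat + k_bmi * P_bmi

with `v0` the net urinary inflow rate (ml/min), `P_age` age (yr), `P_wat`
pre-session water intake (ml), and `P_bmi` body-mass index (kg/m²; its
effect is negligible and the two-covariate model drops it). The package
provides:

- a **seeded synthetic-cohort simulator** (covariates, latent rates,
  noisy BV trajectories with scan-time jitter and post-void residual urine);
- **per-patient rate estimation** by weighted least squares in the
  known-uncertainty (chi-square) convention, with and without scan-time
  uncertainty (effective-variance iteration), and chi-square fit
  probabilities;
- **population-model fitting** by multivariable regression
  (`fit_regression()`) and by an alternating iterative decomposition of the
  covariate effects (`iterative_fit()`), plus Pearson/paired-t comparisons;
- **validation** of model predictions against an independent cohort at a
  relative-deviation tolerance (0.42 by default, derived as the largest
  |mean| + SD deviation envelope across fitting methods);
- a **scan-scheduling simulator**: scan at the predicted fill time, apply a
  rate-correction factor on inconsistent scans, decide void / wait / treat,
  and summarise scan counts and waiting times per fraction;
- an end-to-end **pipeline** (`run_pipeline()`) writing a reproducible
  bundle of CSV/JSON tables and a markdown report.

## Worked example

```r
library(bladderfill)

cfg    <- cohort_config(n_patients = 25, seed = 42)
cohort <- generate_cohort(cfg)
traj   <- simulate_cohort_trajectories(cohort, seq(0, 60, 10), cfg, seed = 43)

fit_inflow_plain(traj[traj$patient_id == "P001", ])
#> Inflow fit (plain): vtot = 1.971 +/- 0.062 ml/min
#>   intercept 18.20 ml; chi2/ndf = 6.347/5 (prob = 0.274); n = 7

records <- estimate_cohort_rates(cohort, traj)
model   <- fit_regression(records, include_bmi = FALSE)
model
#> Inflow-rate model (regression2, n = 25)
#>   v0    = 4.066 +/- 0.64 ml/min
#>   k_age = -0.05737 +/- 0.0092 ml/min per yr
#>   k_wat = 0.006274 +/- 0.0006 ml/min per ml

predict_vtot(model, age = 55, water = 300)       # 2.793 ml/min
predict_first_scan_time(250, 10, 2.793)          # 85.9 min after voiding

simulate_cohort_schedule(cohort, model, noise_cv = 0.05, n_reps = 4, seed = 44)
#> Scheduled 100 fractions: 64.0% one-scan, 99.0% within 3, 100.0% within 5 scans
#>   success 100.0%; wait mean 57.4 min, median 0.0 min
```

The per-patient fit reads: patient P001 fills at 1.97 ± 0.06 ml/min, the
straight line describes the 7 scans well (chi-square probability 0.27). The
population fit recovers coefficients near the generating truth of the
simulator (v0 = 3.115, k_age = −0.047, k_wat = 0.007) from only 25 noisy
patients. With the fitted model guiding the first scan time, most simulated
fractions treat after a single ultrasound scan and almost all within three.

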