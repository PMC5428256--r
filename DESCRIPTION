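Package: bladderfill
Title: Parameterized Bladder-Filling Models for Ultrasound-Guided
    Radiotherapy Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models bladder filling as linear volume growth and links a
    patient's mean urinary inflow rate (ml/min) to age and pre-session
    water intake.  Provides a seeded synthetic-cohort simulator, per-patient
    inflow-rate estimation by weighted least squares with chi-square
    goodness-of-fit probabilities (with and without scan-time uncertainty),
    population-level model fitting by multivariable linear regression and by
    an alternating iterative algorithm, validation of model predictions
    against a relative-deviation tolerance, and simulation of the
    model-guided ultrasound scan-scheduling workflow used to prepare
    patients for pelvic radiotherapy with a consistently filled bladder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
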