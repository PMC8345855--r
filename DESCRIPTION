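Package: tbibaseline
Title: Baseline GCS and Pupil Imputation Strategy Evaluation for TBI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing strategies for deriving a single baseline
    Glasgow Coma Scale (GCS), GCS motor score and pupil-reactivity covariate
    from multi-time-point emergency-phase neurological assessments in
    traumatic brain injury (TBI) cohorts. Implements five substitution
    strategies (working backwards from emergency-department discharge,
    forwards from first presentation, best, worst, and study-hospital
    arrival first) combined with sub-score handling policies for untestable
    verbal and motor components; chained-equations multiple imputation with
    per-variable linear, logistic and proportional-odds conditionals; and
    comparison of logistic (survival) and proportional-odds (GOSE) outcome
    models by McFadden's pseudo-R2. A synthetic-cohort generator with a
    latent-severity construction, untestability and missing-at-random
    masking makes the whole pipeline testable without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
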