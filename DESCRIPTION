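Package: impedScreen
Title: Bioimpedance Spectroscopy Screening with Active Training by Seed Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for a noninvasive type-2-diabetes
    screening device based on electrical bioimpedance spectroscopy.
    Implements gain-factor/system-phase calibration of raw frequency-sweep
    readings against a reference resistor, extraction of a 20-attribute
    feature set (four frequencies by four impedance components plus four
    biometrics), a ridge-regularized logistic-regression screening
    classifier with C-header export for microcontrollers, active training
    by seed selection (ATSS) driven by per-sample silhouette widths and
    performance-indicator gates, a voting predictor with a power-law
    measurement-validity check, Cohen's kappa and Wilcoxon comparison
    protocols, and a synthetic cohort generator that emulates the clinical
    measurement campaign for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, glmnet
Suggests: testthat (>= 3.0.0), e1071, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'features.R'
    'classifier.R'
    'metrics.R'
    'atss.R'
    'predictor.R'
    'synthetic.R'
    'evaluation.R'
    'io.R'
    'cli.R'
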