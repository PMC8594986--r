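# impedScreen

Computational pipeline for noninvasive type-2-diabetes screening from
electrical bioimpedance spectroscopy. The package implements, in R, every
software stage of a portable screening device: calibration of raw
frequency-sweep readings against a reference resistor, reduction of the
calibrated spectrum to a 20-attribute feature vector, a regularized
logistic-regression classifier with C-header export for microcontrollers,
**active training by seed selection (ATSS)** — an active-learning scheme
that builds the training population from high-silhouette samples under
performance-indicator gates — a voting predictor with a power-law
measurement-validity check, and the repeated cross-validated protocol that
compares ATSS against traditional supervised training. A synthetic cohort
generator emulates the clinical measurement campaign (53 participants, 34
women, 20 diagnosed with type 2 diabetes, ages 19–76, ~5 measurements
each, 256 samples) so the whole pipeline is testable end to end without
the request-only clinical data.

## The model in brief

**Calibration.** An AD5933-class analyzer returns dimensionless readouts
(Rr, Ir) per frequency. On a known resistor R_cal the per-frequency gain
factor and system phase are

    FG(f) = (1 / R_cal) / sqrt(Rr² + Ir²),     phase_Z(f) = atan2(Ir, Rr)

and any later measurement is converted by

    |Z| = 1 / (FG · sqrt(Rr² + Ir²)),   phase_C = atan2(Ir, Rr) − phase_Z,
    real = |Z| cos(phase_C),            imag = |Z| sin(phase_C).

**Features.** Four frequencies (10 000, 32 400, 54 800, 77 200 Hz) × four
components (|Z|, phase, real, imaginary) + four biometrics (age, weight,
sex, height) = 20 attributes, screened with per-attribute chi-square tests
and the Hosmer–Lemeshow fit test.

**Classifier.** Ridge-regularized logistic regression P = 1/(1+e^{−h}),
h = w·z + b on z-scored attributes (inverse regularization C = 1).

**ATSS.** Per-sample silhouette widths S_i contrast mean within-class
distance a_i against mean other-class distance b_i (S_i = 1 − a_i/b_i when
a_i < b_i, 0 when equal, b_i/a_i − 1 otherwise). The seed population is
the top 10% of training samples by S_i (stratified per class). Remaining
samples are streamed in random order; a candidate enters the
capacity-bounded population only if (1) its silhouette width exceeds the
population minimum, and (2) retraining does not decrease monitor-set
accuracy while precision or recall strictly increases. At capacity the
lowest-width sample is exchanged.

**Prediction.** 10 repeated measurements; each magnitude spectrum must fit
y = a·x^b with R² ≥ 0.9 to count; a class is returned only if ≥ 80% of
valid measurements agree, otherwise the result is "undefined".

**Evaluation.** 30 repeats of stratified 5-fold cross-validation (grouped
by participant) give 150 paired accuracies per method, compared with a
two-sided Wilcoxon signed-rank test plus Cohen's kappa on pooled
predictions.

## Worked example

```r
library(impedScreen)

cohort <- generateCohort(CohortSpec(labelNoise = 0.15), seed = 42)
nrow(cohort$features)                      # 256 samples, 53 subjects

screen <- chiSquareScreen(cohort$features)
sum(screen$significant)                    # 17 of 20 attributes

model <- trainLogistic(cohort$features)
res <- runAtss(cohort$features, orderSeed = 42)
res$state
#> AtssState: population 22 / 123 samples; 1 commits over 184 candidates
#>   mean silhouette width: 0.6572

rep <- compareMethods(cohort$features, repeats = 5, folds = 5, baseSeed = 42)
rep$summary
#>        method mean_accuracy sd_accuracy
#> 1 traditional     0.7713390  0.09016531
#> 2        atss     0.8197921  0.07830562
rep$wilcoxon_p                             # 0.00298
round(rep$kappa, 3)                        # traditional 0.543, atss 0.646
```

With 15% of participants mislabeled (emulating prediabetic or well-managed
diabetic volunteers), active training beats traditional supervised
training by ~5 accuracy points with a significant paired Wilcoxon test,
and the selected population is far more cohesive than the raw data (mean
silhouette width 0.56 vs 0.20). A voting prediction on 10 repeated
measurements of diabetic participants:

```r
v <- votePredict(model, measurements)      # 10 rows of the feature schema
v
#> VoteResult: diabetic (agreement 1.00 over 10 valid measurements)
```

A command-line interface covering simulate / calibrate / features / train /
predict / evaluate / export / pca lives at `inst/scripts/impedscreen.R`:

```sh
Rscript inst/scripts/impedscreen.R simulate --seed 42 --out cohort.csv
Rscript inst/scripts/impedscreen.R train --data cohort.csv --method atss --out model.json
Rscript inst/scripts/impedscreen.R export --model model.json --out model.h
```

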