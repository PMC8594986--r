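---
title: "Bioimpedance screening with active training by seed selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioimpedance screening with active training by seed selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model and its assumptions, the active-training algorithm and the design
choices that were genuinely open, the synthetic cohort and what passing
tests on it do and do not establish, and the numerical conventions.

## Measurement model

Tissue opposes alternating current with a resistance set by fluid
compartments and a reactance set by cell membranes. An AD5933-class
analyzer sweeps 256 frequencies (10 000 Hz start, 280 Hz increment, 255
steps) and returns dimensionless real/imaginary register values per
frequency. These have no physical meaning until calibrated against a
known resistor (470 Ω here): the per-frequency gain factor
`FG = (1/R_cal)/raw_magnitude` and system phase (four-quadrant angle of
the raw readout) convert any later sweep into magnitude (Ω), calibrated
phase (rad), and real/imaginary parts. Two renderings of the gain-factor
definition are possible from its compact notation; the package uses the
only one under which the calibration readings themselves decode to
`R_cal` — a self-consistency requirement enforced by test. The
single-argument arctangent loses quadrants, so `atan2` is used, and
phases are wrapped to (−π, π]. Calibration is verified against a series
RC phantom (100 Ω + 100 nF), whose closed-form magnitude at 10 kHz is
≈ 187.97 Ω; the error measure is the absolute relative deviation in
percent.

Magnitude spectra of tissue follow a power law `|Z|(f) = a·f^b` (b < 0)
closely over this band. The package exploits this twice: as the
measurement-validity check before voting, and as the generative model of
the synthetic cohort.

## Features and screening

Four frequencies (10 000, 32 400, 54 800, 77 200 Hz) are retained — a
compromise between tissue penetration, statistical tractability, and
microcontroller cost — giving per-frequency blocks of magnitude, phase,
real and imaginary parts plus age (years), weight (kg), sex (0 = female,
1 = male, fixed and persisted with exported models) and height (cm): 20
attributes. Attribute relevance is screened with Pearson chi-square
tests of independence between the binned attribute and the label.
Because the binning is not dictated by the screening's description,
quantile bins (default 4) computed from type-1 quantiles are used: these
are order statistics, so the test is exactly invariant under strictly
monotone transformations of an attribute; attributes with at most 4
distinct values are used as-is. Model calibration is checked with the
Hosmer–Lemeshow test at the conventional 10 risk groups, with
chi-square reference on g − 2 degrees of freedom; groups require at
least 2 samples and zero expected counts either fail or merge, per
configuration.

All distance-based computation (silhouettes) and classification runs on
z-scored attributes, with the scaler learned on training data only —
distances across Ω, years and kg are meaningless otherwise.

## Classifier

A ridge-regularized logistic regression, `P = 1/(1 + exp(−(w·z + b)))`,
fitted with glmnet (`alpha = 0`, `lambda = 1/(n·C)`, default `C = 1` in
the inverse-strength convention). The mild default ridge keeps fits well
defined on small, linearly separable populations such as the seed
(around 20 samples of 20 attributes). The decision threshold is 0.5
unless configured. Models serialize to JSON (language-neutral) and to a
C header (`W`, `B`, `MU`, `SIGMA`, `N_FEATURES`) from which firmware
reproduces predictions; 9 significant digits preserve float32 precision
and the round-trip is verified to 1e−5 in probability.

## Active training by seed selection

Per-sample silhouette widths use the mean Euclidean distance to own-class
samples (a_i) versus the other class (b_i); widths near 1 mark firmly
embedded samples, negative widths mark samples sitting in the wrong
class's territory — mislabeled or atypical participants. The algorithm:

1. Hold out a stratified monitor fraction (default 0.2) of the training
   data for indicator evaluation.
2. Seed: the top `ceiling(0.10·n)` pool samples by silhouette width.
   Selection is stratified per class with proportional seats (largest
   remainder, minimum two per class) — global top-k could yield a
   one-class seed, on which no classifier can be fitted.
3. Stream the remaining pool samples in a seeded random order. A
   candidate must (rule 1) have a silhouette width, measured against the
   current population, above the population minimum — otherwise it is
   rejected without retraining; then (rule 2) retraining on the
   tentative population (append below capacity, else exchange against
   the minimum-width member, ties broken by earliest entry) must not
   decrease monitor accuracy while precision or recall strictly
   increases. Rejected tentatives are reverted; every decision is logged
   with its indicator deltas, so a run's history replays both rules.

Design points that were genuinely open, and how they were resolved:

* **Monitor set.** The data on which the indicator gates are evaluated
  is not pinned down by the algorithm's description; a held-out
  stratified fraction (0.2) was chosen so the gates measure
  generalization rather than fit to the population being built.
* **Gate strictness.** "An indicator must increase" is read strictly
  (ties reject — a duplicate sample that changes nothing is refused).
  With a smooth ridge classifier this makes the gate very conservative:
  adding one sample rarely moves count-based indicators on a small
  monitor, so most growth attempts fail rule 2 and the final population
  stays close to the seed. A configurable `"nondecreasing"` gate lets
  the population grow toward capacity; in our synthetic experiments it
  admitted class-imbalanced drift and degraded accuracy, so the strict
  reading remains the default.
* **Candidate silhouette reference.** The candidate's own width is
  identical whether or not the candidate is counted into the reference
  population (its self-distance is excluded from a_i either way), so the
  "including the candidate" convention costs nothing.
* **Capacity.** A cap exists to bound retraining cost; its value is not
  specified. Default: 60% of the pool.
* **Indicator comparisons** round to 1e−12 first, so floating-point
  noise can neither admit nor reject a candidate.
* Rejected candidates are not re-offered.

The monitor-accuracy sequence along commits is non-decreasing by
construction — an invariant the test suite replays from history logs.

## Voting prediction

Ten repeated measurements per participant. Each magnitude spectrum is
fitted with `log y = log a + b·log x`; measurements with R² below 0.9
(configurable, recorded in output) are excluded — the power-law check
catches electrode slip and motion artifacts, which corrupt the spectrum's
shape. Each valid measurement is classified; the modal class wins only
with a share ≥ 0.8 (closed comparison: 8/10 passes), otherwise the
result is "undefined". Fewer than 5 valid measurements always yield
"undefined" with an explicit reason. Agreement is computed over valid
measurements only; the decision is invariant to measurement order, and
raising the threshold can only move a decision toward "undefined".

## Synthetic cohort

The generator emulates the clinical campaign's statistical structure: 53
participants (34 women), 20 diabetic, ages 19–76, ~5 measurements each,
exactly 256 emitted samples (measurements allocated floor + round-robin,
since 53·5 ≠ 256). Per subject, a power-law spectrum with the diabetic
class's coefficient `a` scaled by `classEffect` (default 1.5, diabetics
less conductive, hence higher impedance), diabetics on average older
(+10 years) and heavier (+8 kg). The phase is a smooth small negative
function of frequency — a synthetic convention, since nothing constrains
the phase distribution and no acceptance property depends on it.

Within-class variation is deliberately multi-dimensional, as in real
forearm measurements:

* subject-level spread of the power-law coefficient (log-sd 0.08) and
  exponent (sd 0.005) — body composition;
* subject-level per-frequency deviations from the pure power law and
  phase-shape variation (sd 0.04, scale factor sd 0.10) — anatomy and
  electrode site;
* per-measurement session effects (log-sd 0.03) — electrode placement
  and contact, larger than the within-session repeatability;
* per-point multiplicative noise (`noiseSd`, default 0.02) — instrument
  noise, calibrated so the repeated-measurement stability series shows
  ~2% relative standard deviation per hourly session, the device's
  observed repeatability.

The first two spreads were calibrated once so that the default class
effect of 1.5 with 2% noise yields cross-validated accuracy above 0.9 on
clean labels — the separability the cohort is specified to emulate. The
multi-dimensional nuisance matters for a structural reason: if
within-class variation is confined to the discriminative axis, the
highest-silhouette samples are exactly the most extreme ones, the worst
case for fitting a boundary from selected samples, and no
sample-selection scheme can look good. With realistic nuisance, high
silhouette instead means "low-nuisance prototype", which is what the
seed-selection idea presumes.

Label noise (`labelNoise`, default 0) flips the *recorded* label of that
fraction of subjects — whole subjects, not single measurements — leaving
the generating physiology untouched. This mirrors the clinically
described confounders: prediabetic volunteers with diabetic-like
impedance but no diagnosis, and well-managed diabetics whose tissue
looks healthy. `noiseSd = 0` switches to an idealized mode (all nuisance
off) in which every emitted spectrum is an exact power law and the
subject's (a, b) is recoverable to 1e−9.

What passing tests on this cohort show: that the pipeline's mechanics
are correct and that the qualitative comparison claim — active training
beating traditional supervised training under label noise, both
exceeding 90% accuracy on clean separable data — is reproduced under the
stated conditions. What they do not show: anything about real tissue.
The generator has no Cole–Cole dispersion, no glucose dynamics, no
instrument drift, and its nuisance magnitudes are plausibility choices,
not fitted to measurements.

## Evaluation protocol

30 repeats of stratified 5-fold cross-validation give 150 paired
accuracy values per method; repeats differ in fold assignment and ATSS
streaming order, both derived from the base seed, so reports reproduce
bit for bit. Splits are grouped by participant by default: a subject's
~5 repeated measurements are near-duplicates, and letting them straddle
a fold boundary lets any classifier score by memorizing subject
profiles (the null-cohort test demonstrates this leak directly). The
paired lists are compared with a two-sided Wilcoxon signed-rank test —
exact enumeration of the sign-flip distribution (dynamic programming
over midranks, valid under ties) up to 25 nonzero differences, corrected
normal approximation beyond — and Cohen's kappa is computed on pooled
test-fold predictions. The silhouette summary reports the mean width of
the full data, of the seed populations, and of the final populations.
PCA (top two components of the standardized attributes) is a
visualization aid only.

Problem sizes used throughout the test suite and the acceptance script —
the 256-sample default cohort, 30×5-fold comparisons, oracle checks on
up to 200 random instances of n ≤ 50 — were chosen to exercise every
code path at the study's own scale while keeping a full run in the
minutes range on one CPU.

## Numerical conventions and degenerate inputs

* Phases wrapped to (−π, π]; spectra validate real² + imag² = |Z|²
  to 1e−9 relative.
* Zero raw magnitude: degenerate calibration (error names the
  frequency); zero theoretical value: undefined error percentage.
* Undefined indicator ratios (0/0) are reported as absent (`NA`), never
  as 0; undefined voting outcomes are excluded from confusion counts and
  reported separately.
* Kappa with degenerate identical marginals is 1 when agreement is
  perfect.
* Constant attributes: chi-square p = 1; standardization maps them to
  exactly zero (sd substituted by 1).
* Power-law fit of a constant spectrum returns b = 0 with R² = 1 (zero
  residual and zero total variation).
* Silhouettes require at least two samples per class; one-sample classes
  are a documented error, not NaN.

## Known limitations

* The strict indicator gate makes ATSS behave mostly as "train on the
  high-silhouette seed"; its advantage under label noise comes from
  training on a clean, prototypical subset rather than from population
  growth. Alternative gate semantics are exposed but not default.
* Two-class problems only; no concept drift, no re-offering of rejected
  samples, scaler frozen at seeding.
* Calibration supports a purely resistive reference only.
* The synthetic cohort is a statistical emulation; transferring
  conclusions to clinical data requires the real measurement campaign.
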