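---
title: "Methods: scoring, classification and the synthetic-cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classification and the synthetic-cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icatest)
```

`icatest` implements a rapid visual categorization test of information
processing speed — the kind used as a digital cognitive biomarker in
multiple sclerosis — together with its scoring pipeline, an impairment
classifier, the validation psychometrics, and a synthetic-subject simulator
that stands in for patient data. This vignette documents the models and the
choices made where the published description of such platforms leaves the
design open.

## Test materials

**Backward masks.** A single white-noise image is low-pass filtered at four
octave-spaced Gaussian scales (σ = 8, 4, 2, 1 px on a 256 px canvas, scaled
with canvas size; scale 1 is the coarsest) and each filtered image is
thresholded at its own median, giving four high-contrast binary patterns
with ~50/50 pixel coverage. Each pattern is expanded into four variants —
90° and 180° rotations, horizontal and vertical mirrors — for a pool of 16
frames (4 scales × 4 variants). Two open choices are resolved here: the
filter family (we use Gaussian low-pass, the standard coarse-to-fine
noise-mask construction) and the variant set (the unrotated original is
excluded, since four variants per scale are needed to reach 16 frames). A
dynamic mask is 8 frames drawn from the pool with each scale appearing
exactly twice, shown for 250/8 = 31.25 ms each — the only division
consistent with an 8-frame, 250 ms mask.

**Stimuli.** Real photographic stimulus sets are copyrighted, so the package
draws procedural stand-ins: organic radial-harmonic silhouettes ("animal")
versus straight-edged geometric figures ("non-animal") composited over
low-pass noise clutter. The main set has 100 images (50 per label); two
disjoint 10-image practice sets (5 per label) serve the practice gate. Each
image carries a difficulty scalar in [0, 1] — harder images have smaller,
lower-contrast targets in heavier clutter — spread evenly over [0.05, 0.95]
within each label so every administration samples the full range. The
difficulty scalar, not the pixels, is what the simulator consumes; the
pixels exist so the full I/O path (PNG export, manifests) is exercised.

**Schedule.** One administration presents every main image exactly once in a
seeded random order (re-randomized per administration), with 100 ms image,
20 ms inter-stimulus interval, and a fresh 250 ms mask per trial.

## Session logic

A session starts with a 10-image practice block. Strictly more than 50%
correct (6/10) passes; exactly chance (5/10) or below triggers one retry
with the second practice set; failing both aborts the session. Practice
trials are tagged by phase and never reach the scorer. Non-responses are
recorded as `response = "none"`, count as incorrect, and contribute no
reaction time — this keeps the accuracy denominator at the full trial count.
Sessions persist as schema-versioned JSON; loading validates every record
(e.g., a responded trial without an RT is reported with its trial index).

## Scoring

With per-trial responses and reaction times (RT, ms) on the main phase:

1. **Outlier removal.** Tukey fences at whisker width w = 1.5 over the
   responded trials' RTs: an RT strictly above q3 + w·(q3 − q1) or strictly
   below q1 − w·(q3 − q1) marks its trial as an outlier. Quartiles use
   linear interpolation between order statistics (R type 7) — documented so
   the fences are exactly reproducible. Outlier trials are removed from
   *both* the accuracy denominator and the RT pool: the validity rule is
   phrased in terms of observed images, which implies trial-level removal.
   A session with more than 40% outlier trials is flagged invalid (exactly
   40% is still valid, reading "exceeds" strictly).
2. **Accuracy** = 100 × correct / retained trials.
3. **Speed** = min(100, 100·exp(−meanRT/1025 + 0.341)) over correct retained
   trials. The bracketed two-element form this formula is usually quoted in
   is read as a cap: speed equals 100 for mean RTs up to
   1025 × 0.341 = 349.525 ms and decreases strictly beyond, which keeps both
   speed and the composite bounded at 100 as the published score ranges
   require.
4. **Composite** = (speed/100 × accuracy/100) × 100.
5. **Trends.** Ordinary least-squares slopes of per-trial correctness (0/1)
   and of the per-trial speed transform (the speed formula applied to each
   correct trial's RT) against trial index, on retained trials. The slope is
   the simplest estimator whose sign answers "increasing or decreasing
   during the test"; `trend_window` (default 10) is the minimum trial count
   before a slope is attempted.

A consequence of the fence construction worth knowing: at most ~25% of
points can lie beyond one fence (the 75th percentile sits inside any larger
one-sided cluster), so the >40% invalidity rule can only trigger with
two-sided contamination. The test suite exercises it accordingly.

## The impairment classifier

Features, in fixed order: composite score, accuracy trend, speed trend, age,
gender (0 = male, 1 = female), education in years. Trends enter as raw
slopes (rather than categorical increasing/decreasing flags) and
demographics are standardized together with the score features — both open
choices, resolved toward the simplest model.

The classifier is a multinomial (softmax) logistic regression, retained in
softmax form so the same machinery covers more than two status labels.
Features are z-scored by their training means and population SDs; weights
minimize the per-observation mean negative log-likelihood plus
(λ/2)·‖W‖² on non-intercept weights, λ = 1.0 by default — enough to
stabilize the many small-n fits of leave-one-out cross-validation. The
objective is convex and solved by BFGS with an analytic gradient (tolerance
1e−10), so fits are deterministic. Averaging the likelihood (and using
population SDs in the scaler) makes the fitted boundary exactly invariant to
duplicating the training set.

Evaluation is leave-one-out: subject i is scored by a model fitted — scaler
included — without subject i, so no information leaks from the held-out row.
The ROC sweeps thresholds over the unique held-out probabilities; its
trapezoid area equals the pairwise concordance probability with ties counted
half (asserted against that oracle in the tests). The reported operating
point maximizes Youden's J, a reasonable default when a single
sensitivity/specificity pair must be quoted without a stated rule.

## Psychometrics

- **Impairment rule:** impaired iff any subtest z ≤ −2 or at least two
  subtests z ≤ −1, with z against a user-supplied norms table. Boundaries
  are inclusive — conservative toward impairment detection. The bundled
  default norms are the healthy-control summary statistics from the
  reference table, since the external normative dataset behind such studies
  is not published.
- **Cohen's d** uses the simple-average pooled SD
  √((s_a² + s_b²)/2), the variant that reproduces the reference table's
  printed effect sizes for SDMT, BVMT-R, accuracy and the composite score to
  two decimals. (Two rows of that table — speed and CVLT-II — are off by
  0.01–0.02 from every standard variant and are not asserted. The table's
  composite-score difference cell is also inconsistent with its own printed
  means; the means are authoritative here, and they reproduce the printed
  d = 1.26.)
- **Pearson r** carries the exact two-sided t-transform p-value;
  **test-retest** bands reliability strictly: r > 0.70 adequate,
  r > 0.80 good.
- **Composite z** averages the three subtest z-scores against the cohort's
  own moments, so its cohort mean is 0 by construction.
- **Paired comparisons** report mean difference / SD of differences as the
  paired d; identical vectors short-circuit to d = 0 with an undefined t
  rather than failing.

## The synthetic-cohort model

The simulator exists so every module is testable at study scale with no
data download. It is a generative stand-in, not a cognitive model.

**Response model.** Per trial,
P(correct) = (1 − lapse)·logistic(ability − 4·(difficulty − 0.5)) + lapse/2;
RT = shift + exp(μ_RT + 0.3·difficulty + drift + ε), ε ~ N(0, σ²), with
defaults shift = 200 ms, σ = 0.25, lapse = 0.02. With probability
`outlier_prob` (default 0.01) an RT is replaced by a uniform contaminant on
[3000, 10000] ms, exercising the fence and validity machinery. The
difficulty–RT coupling (0.3 log-ms per difficulty unit) makes harder images
slower, consistent with the task's difficulty gradient.

**Latent structure.** A standard-normal latent cognitive factor z drives
everything: battery subtests load on it at 0.8 (chosen to reproduce the
published score–SDMT correlation of ~0.8); it loads on standardized age at
−0.45 and education at +0.25 (reproducing the published score–age and
score–education correlations of about −0.49 and 0.25); task ability and
log-RT are linear in z; and a fatigue term — per-trial ability and log-RT
drift proportional to logistic(−z) — makes low-ability subjects deteriorate
within the session, which is what gives the classifier's trend features
signal. Serum NfL for patients is β0 + β1·score + noise with the noise SD
set so the population correlation is about −0.79, the published association.
All couplings were fixed once against those published statistics.

**Calibration.** `calibrate_group_params()` matches a group's simulated
composite-score mean and SD to targets (by default the bundled reference
moments: patients 63.67 ± 13.30, controls 78.43 ± 9.86) by iterated moment
matching: a damped Newton step on mean ability against the accuracy
component, a log-secant step on mean log-RT against the speed component, and
a ratio step on the latent spread against the SD. Each iteration simulates
3000 subjects' main tasks with a vectorized version of the same trial model
and scores them with the production fences and formulas; iterations draw
fresh Monte Carlo replicates so the matched moments are not an artifact of
one sample, convergence requires two consecutive in-tolerance replicates
(±1.0 on the mean, ±1.5 on the SD), and the result is verified on a 9000
subject replicate. Unattainable targets — e.g., a mean at the score cap with
zero SD — fail with the achieved moments attached. The shipped group
defaults in `group_params_defaults()` are the output of this procedure.

**What the simulator does and does not establish.** Simulated cohorts
reproduce the published group score moments, demographic structure,
convergent-validity and biomarker correlations, and test-retest behaviour
(no learning effect is modelled: a retest reuses subject parameters with a
fresh presentation order, the published design for repeat administrations).
Impairment prevalence among simulated patients comes out near 55–60%
against the bundled norms — the published 45% is matched only approximately,
as the external norms behind that figure are unknown. Real data differ in
ways the generator does not attempt: RTs are not really shifted-lognormal,
errors are not exchangeable given difficulty, fatigue is not linear, and
impairment is not a deterministic function of three subtests. Passing
pipeline tests on these cohorts therefore demonstrates the *machinery* —
scoring, leakage-free cross-validation, calibration — not clinical validity.

## Problem sizes and numerical choices

The test suite simulates full-scale cohorts (91 + 83 subjects, 100 main
trials each) where group-level claims are checked: 10 cohort replicates for
the cross-validated AUC property (each AUC ≥ 0.85 at the shipped
calibration) and 20 replicates for group separation, whose mean Cohen's d is
required within ±0.25 of the reference 1.26 — a per-replicate band would be
unsound, since d's sampling SD at these group sizes is ~0.17. Smaller
canvases (32–64 px) are used for image fixtures; nothing under test depends
on resolution. Degenerate inputs are handled explicitly: zero-IQR fences
remove nothing (strict inequalities), constant features are rejected by the
classifier with the feature named, single-class labels and undersized
practice blocks are errors, and scoring refuses aborted sessions with a
dedicated condition class.

## Known limitations

- The stimulus generator's difficulty scalar is prescribed, not estimated;
  no attempt is made to validate that the drawn images are psychophysically
  calibrated.
- The response model has no response deadline (the platform's timeout
  behaviour is unspecified), so simulated sessions contain no
  non-responses, although the scoring path for them is implemented and
  tested.
- One-sided RT contamination above ~25% of trials cannot trip the 40%
  invalidity rule (a property of Tukey fences, not of this implementation);
  only two-sided contamination can.
- The classifier's λ, the fatigue scales, and the latent loadings are
  defensible defaults calibrated to published summary statistics, not fitted
  quantities; conclusions sensitive to them should be checked across a range.
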