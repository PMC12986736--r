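---
title: "Quantifying tongue lateralization kinematics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tongue lateralization kinematics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tonguekin)
```

## The measurement problem

In motor-neuron disease, bulbar involvement degrades the speed and range
of voluntary tongue movements before routine ordinal scales register a
change. A cheap, objective probe is a short video task: the participant
protrudes the tongue and moves it side to side as fast as possible for
at least five seconds while a phone camera (30 frames/s) films the
perioral region. `tonguekin` implements the full measurement chain for
this task -- semantic segmentation of the tongue, tip tracking, cycle
counting and feature extraction -- together with the statistics used to
validate the resulting biomarker at cohort level, and a synthetic-data
module that makes every stage testable without access to patient video.

## Kinematic model

Each frame's binary tongue mask is reduced to a single lateral
coordinate: the *tip*, operationally the most lateral mask pixel along
the horizontal axis. The clip-wide baseline is the median of the mask
centroid columns; per frame the leftmost and rightmost mask columns are
candidate tips and the one farther from baseline wins (ties resolve
leftmost). Displacement is `(x_tip - baseline) * mm_per_px`, signed,
rightward positive.

From a displacement series over a scoring window of `T = 5` s the
package computes

* `frequency = Ncycles / T` (Hz), where `Ncycles` counts *complete*
  lateral cycles;
* `max_amplitude = max |d(t)|` (mm), the greatest lateral displacement;
* `normalized_frequency = frequency / max_amplitude` (Hz/mm), the
  primary biomarker, which compensates inter-individual differences in
  anatomy and movement range.

Subjects perform the task twice and the subject-level value is the mean
of the two trials.

### Cycle counting

A cycle is one full left--right--left (or right--left--right) excursion.
The counter mean-centres the signal, smooths it with a 5-frame centred
moving average (~167 ms at 30 fps -- wide enough to kill single-frame
segmentation jitter, narrow enough to pass oscillations of a few Hz),
and applies a hysteresis state machine with thresholds at `+/- h`, `h =
0.2 * max|d|`. Each threshold crossing on the side opposite the previous
one is an alternation; two alternations complete a cycle; the final
partial cycle is discarded. This floor-like behaviour means a noise-free
sinusoid of frequency `f` scores exactly `floor(5 f)` cycles when
started at phase zero, which the tests exploit as an analytic oracle.
The count is invariant to sign flips, constant offsets, and zero-mean
noise with SD below `h/3` (tested properties).

### Guards and quality control

Near-zero amplitudes would blow up the normalized ratio, so amplitudes
below 1 mm abort with an explicit error; the synthetic cohorts never
produce them, mirroring the empirical absence of near-zero amplitudes in
the clinical recordings this design models. Frames with an empty mask
are linearly interpolated and flagged; runs longer than 10 frames
(~333 ms) fail the clip, standing in for exclusion of recordings whose
blur prevents reliable segmentation. The spatial calibration
`mm_per_px` must always be supplied explicitly (0.25 mm/px at a 256-px
working width by default in the generators, a ~6.4 cm field of view); it
is never inferred from image content.

### Scoring window

The task asks for at least five seconds of movement, so which five
seconds are scored is a genuine design choice. We score from movement
onset (the first smoothed sample beyond the hysteresis threshold) when
at least 5 s remain, otherwise from the clip start, warning only when a
meaningful onset (> 0.5 s) had to be discarded. Maximum amplitude is
the one-sided maximum from baseline, not peak-to-peak: the greatest
displacement achieved is a single displacement, not a range, and the
choice is documented and configurable.

## Segmentation model

The segmenter is a U-Net++: an encoder--decoder whose skip pathways form
a dense nested grid. Node $X^{i,j}$ (level $i$, nested depth $j$)
receives every same-level predecessor $X^{i,0..j-1}$ plus the upsampled
output of $X^{i+1,j-1}$; each node is two 3x3 convolution + batch
normalization + ReLU stages (running BN statistics are accumulated
during training and used at inference). The head is a 1x1 convolution
with sigmoid output. The full-scale
training recipe is 256x256 inputs normalized to [0, 1], Adam at 1e-4,
batch 16, 100 epochs, and an equally weighted sum of binary
cross-entropy and soft-Dice loss (smoothing constant 1); probability
maps binarize at 0.5. All of these are explicit `seg_train_config`
fields. Because no deep-learning framework ships with this package's
target environment, the convolutional primitives are implemented
natively (im2col-free shifted-view GEMMs on BLAS) with exact
hand-derived backpropagation, verified against finite differences in the
test suite.

Evaluation is participant-grouped k-fold cross-validation: participants
(never images) are shuffled under the run seed and dealt round-robin
into folds, so every image is validated exactly once and no participant
appears on both sides of a fold. The absence of overlap is asserted at
run time, not sampled. Overlap is scored by Dice and IoU with the
conventions both-empty = 1 and one-empty = 0; `dice = 2*iou/(1+iou)`
holds exactly per image. Diagnostic labels have no representation in the
training interface, and a dataset object carrying a `group` field is
rejected.

### Reduced-scale profile

`desk_profile()` is the package's single-CPU benchmark configuration:
128-px inputs, width multiplier 1/4 (base 8 filters), depth 3, 2 grouped
folds, 15 epochs, same optimizer and loss as the full recipe. Training
this short produces probability maps that discriminate tongue from
background well but remain under-confident: held-out Dice is high and
stable across binarization thresholds from ~0.3 to ~0.5 and collapses
just above, because the maximum predicted probability has not yet
saturated. The profile therefore enables `calibrate_threshold`: after
training each fold, the binarization threshold is chosen to maximize
mean Dice on that fold's *training* images (a standard operating-point
calibration; the held-out fold is never consulted, so the grouped-CV
protocol is intact). At full scale the fixed symmetric threshold 0.5
remains the default. U-Net++ deep supervision stays off in both
profiles: averaging several early side outputs dilutes the head
gradients and demonstrably slows convergence at this step budget.

## Synthetic data: what it emulates and what it does not

The generator family exists because the study's recordings are private;
it reproduces the *conditions* of the study so that every algorithmic
claim is testable.

* **Task clips** (`render_clip`): an elliptical tongue with a smooth
  low-order cosine boundary perturbation whose centre follows
  `A sin(2 pi f t + phase)` over a two-tone face/mouth background, with
  illumination jitter, pixel noise, optional slow jaw drift, and
  per-frame ground-truth masks that exactly cover the rendered tongue.
  The ground-truth tip series is derived from the continuous shape
  geometry (lateral extents and centroid of the perturbed ellipse), so
  the mask-based tracker can be held to a 1-pixel RMS match. Rendering
  is bit-deterministic under a seed.
* **Segmentation datasets** (`generate_segmentation_dataset`):
  image/mask pairs with randomized shape, pose, scale, colour,
  illumination, blur, noise and background; several images share a
  participant key with consistent appearance, exercising grouped CV.
* **Cohorts** (`simulate_cohort`, `simulate_kinematic_cohort`): group
  presets calibrated to the published summary statistics -- normalized
  frequency means 0.138 (patients) and 0.395 (controls) Hz/mm, sign
  prevalences 30%/38%/19%, ages 63.9 +/- 12.4 and 61.1 +/- 9.1 -- with
  the speech item generated from the published regression coefficients.

Design choices the data do not pin down, and how we resolved them:

* **Within-group SD of normalized frequency.** Group SDs are not
  published. We invert the pooled two-sample t formula at the published
  `|t| = 9.58` and group sizes 37/20, giving a common SD of ~0.0967
  Hz/mm (`derive_common_sd`); the inversion is unit-tested against a
  direct t computation on samples with exactly those moments. This is a
  modelling choice, not a published value.
* **Positive-support distributions.** Normalized frequency and
  amplitude are Gamma with matched mean and SD rather than normal:
  draws must be positive and mild right skew is realistic. Amplitude
  means default to 10 +/- 2 mm (patients) and 7.5 +/- 1.5 mm (controls),
  chosen so the implied cycle frequencies (~1.4 and ~3 Hz) sit in the
  physiological range.
* **Cycle grid.** A subject's realized frequency is snapped to the
  complete-cycle grid `round(5 f)/5` with at least one cycle: the
  measured frequency is by definition a whole number of complete cycles
  per 5 s, and snapping (rather than truncating) keeps the group mean of
  the *measured* biomarker centred on the preset mean instead of
  inheriting a floor bias of up to 0.2 Hz.
* **Frequency ceiling.** Independent draws of normalized frequency and
  amplitude occasionally imply implausible oscillation speeds (> 5 Hz);
  amplitude is shrunk until the implied frequency is at most 4.5 Hz.
  The subject's normalized frequency is unchanged by this adjustment;
  it removes tail subjects that no instruction-following human would
  produce and that alias against the 30-fps sampling.
* **Speech noise calibration.** The residual SD of the speech-score
  model is set so the generating model's population R^2 equals the
  published 0.508: `sigma^2 = Var(X beta) (1 - R^2)/R^2`, with
  `Var(X beta)` computed analytically from the preset covariate
  distributions. The unclamped continuous score (`speech_latent`) is
  retained alongside the clamped (`speech_score`) and rounded ordinal
  (`speech_ord`, half-away-from-zero then clamped to 0..4) copies;
  recovery tests fit the latent copy, because clamping is a property of
  the ordinal instrument, not of the generating model.

What the synthetic data deliberately does not model: photorealistic
appearance, anteroposterior (swallowing-related) motion, chin/head
compensation, and real annotation noise. Passing tests therefore
demonstrate correctness of the measurement chain and statistics under
controlled conditions, not clinical performance on real video.

## Statistical plan

`compare_groups` runs the pooled Student t-test as primary (Welch
alongside). The normality gate is Lilliefors-type KS (parameters
estimated) combined with |skewness| > 2; if either group fails, the
Mann--Whitney U result is reported with the parametric result retained
in diagnostics. The gate's KS variant is a design choice; two-sided
tests throughout; no multiple-testing correction, matching the
hypothesis-driven analysis plan this package mirrors.

`fit_speech_model` is OLS of the speech score on age, normalized
frequency, spasticity, fasciculations and jaw jerk, with Student-t CIs
at `n - k - 1` df, VIFs, and Shapiro/Breusch--Pagan diagnostics.
Collinear designs error out naming the offending predictors.

`bootstrap_optimism` implements Harrell's internal validation: refit on
each resample, optimism = (bootstrap-sample R^2) - (bootstrap
coefficients scored on the original sample), corrected = apparent -
mean optimism; degenerate resamples are skipped and counted. Internal
validation by 1000-iteration bootstrap does not by itself pin down an
optimism-correction variant; Harrell's procedure is our choice.

`ordinal_sensitivity` refits the model as a proportional-odds
cumulative-logit regression on the ordinal item, reports Wald p-values,
flags (quasi-)separation, and states whether the normalized-frequency
effect agrees with OLS in sign and significance.

## Problem sizes used by the validation suite

The packaged checks run at sizes chosen for a single CPU: kinematic
cohorts of 200 subjects per group (with 10,000-subject precision runs
where two-decimal rounding of a group mean is asserted), a 120-image
segmentation benchmark at 128 px under the reduced-scale profile,
regression cohorts of 2,000 subjects, and 200 replicate cohorts for the
t-statistic recovery. The full-scale training recipe (256 px, width 1,
depth 4, 100 epochs, 5 folds) is exposed as the default configuration
but is not exercised by the automated checks.

## Known limitations

* The segmenter is validated on synthetic scenes; no claim is made about
  real-image performance, and no pretrained weights ship with the
  package.
* Cycle counting assumes an approximately stationary oscillation inside
  the scoring window; pathological movement patterns (long pauses,
  drifting baseline beyond the jaw-drift model) are only partially
  represented by the generator.
* The bootstrap and ordinal analyses assume subject-level exchangeability
  and at least two observed outcome levels respectively; both error or
  flag rather than silently proceed when violated.
* MP4 decoding is out of scope: clips enter as PNG frame directories or
  in-memory arrays (video codec availability varies too much across
  deployments; the container frame rate must be supplied as `fps`).
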