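---
title: "Digital eye-tracking biomarkers for ADHD screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital eye-tracking biomarkers for ADHD screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculomark)
```

## The assessment paradigm

`oculomark` analyzes screen-based gaze recordings of three saccade tasks
commonly used to probe attention and inhibitory control in school-aged
children:

* **prosaccade** — look at a suddenly appearing stimulus (baseline reflexive
  orienting);
* **antisaccade** — look at the location mirror-opposite the stimulus
  (inhibition of the reflexive saccade plus symmetric localization);
* **delayed saccade** — keep fixating the central cross while the stimulus is
  visible, and move only after an auditory cue (go/no-go-style response
  suppression with audiovisual integration).

Each trial starts with a central fixation cross; the stimulus (a 5 x 5 cm
square) appears 1500 ms later at one of six positions — 7, 15 or 20 degrees
of visual angle left or right of the center. In the delayed task the go-cue
sounds 1000 ms after stimulus onset (2500 ms into the trial) and the trial
ends 3000 ms later; in the other two tasks the trial ends once gaze has dwelt
in the target region for 300 ms, or at a 5 s timeout. Each task presents 12
formal trials (every position twice). The default physical model is a
24-inch 1920 x 1080 monitor (53.14 x 29.89 cm) viewed from 65 cm; degrees are
converted to pixels with the flat-screen tangent model
`offset = d * tan(theta)`, which is exact for a flat display.

## Areas of interest

Fixations are labeled by a partition of the screen built per trial:

* **CA** — a 5 x 5 cm square around the central cross;
* **SA** — the stimulus square; **TA** — the target square (identical to SA
  in the prosaccade and delayed tasks, its horizontal mirror in the
  antisaccade task);
* a horizontal **band** of height 5 cm centered on the stimulus axis holds
  the task-relevant space; everything outside the band is the unrelated area
  **UA**;
* in the antisaccade task the band's remaining space splits at the vertical
  midline into the proper-side area **PSA** (target side) and the wrong-side
  area **WSA** (stimulus side); in the other tasks it belongs to UA.

The exact shapes of UA/PSA/WSA are a design choice of this package (the
band-based construction above): the published figures defining them are not
machine-readable, so the geometry is configurable and the defaults are
declared rather than inferred. Rectangles are half-open in 0-based pixel
coordinates (origin top-left), so every on-screen pixel receives exactly one
label; a point on a shared edge belongs to the rectangle on its right/below,
which removes tie ambiguity.

Delayed-saccade trials add a time dimension: a fixation starting in
`[0, 1500)` ms that leaves CA is an *intrusive saccade*; a TA fixation
starting in `[1500, 2500)` ms (stimulus visible, cue pending) counts toward
`N_TA-W_Fix` (wrong period) and one starting after the cue toward
`N_TA-P_Fix` (proper period).

## Event detection

The study relied on vendor software for fixation/saccade classification;
this package re-implements the velocity-threshold (I-VT) algorithm so the
pipeline runs without proprietary tools. Gaze positions are converted to
visual angles, smoothed with a centered 3-sample moving average, and
differentiated centrally; samples whose angular velocity exceeds 30 deg/s
are saccade samples, the rest fixation samples. Contiguous runs become
events; fixations shorter than 60 ms are discarded; gaps of missing data up
to 75 ms inside an event are bridged while longer gaps split events. The
defaults (30 deg/s, 60 ms, 75 ms) are the vendor's published filter
defaults; all are configurable via `ivt_config()`. Binocular position is the
average of the valid eyes, with one-eyed samples using the valid eye.

On noise-free synthetic trajectories the detector recovers event boundaries
within two samples; the suite asserts this. Participants are retained for
analysis only when strictly more than 80% of their samples carry at least
one valid eye.

## Pupillometry preprocessing

Pupil traces are preprocessed in five steps, separately per eye for steps
1-2:

1. drop invalid samples and diameters outside the feasible 1.5-9.0 mm range
   (inclusive bounds);
2. compute the normalized dilation speed
   `s_i = max(|Δp/Δt| backward, |Δp/Δt| forward)` (endpoints use their single
   one-sided speed — the definition is silent there, and the one-sided speed
   is the only information available), then remove samples with
   `s_i > median(s) + 1.5 * MAD(s)`, where `MAD = median(|s - median(s)|)`.
   "Larger than" is read strictly, so when `MAD = 0` only samples strictly
   above the median speed are removed;
3. keep timestamps surviving in both eyes and average the two diameters;
4. resample onto a uniform 500 Hz (2 ms) grid: each output value is a
   timestamp-weighted exponential moving average over at most the 20 nearest
   preceding samples. The decay half-life defaults to 10 ms (the source
   procedure specifies the window size but not the decay constant; 10 ms
   damps sensor noise without smearing the light reflex). Data gaps of 50 ms
   or more split the trace into segments and no value is synthesized inside
   or across a gap. The window is counted in samples (the literal reading of
   "size 20 sliding window"); both the size and the interpretation are
   configurable;
5. summarize the uniform trace into the four pupil biomarkers: mean,
   maximum, minimum and SD of diameter. The SD uses the sample (n-1)
   denominator, the convention of the analysis software the study used.

## The biomarker catalog and feature table

Twenty-eight per-trial biomarkers are defined (8 general, 4 pupil-based, 11
area-based, 3 search-based, 2 entropy-based); `biomarker_catalog()` is the
canonical enumeration with each metric's task applicability. Three call for
explanation:

* **Fixation latency** `L_TA_Fix` is measured from the response-permitting
  event: stimulus onset for prosaccade/antisaccade trials and the auditory
  cue for delayed trials, since no earlier response is permitted.
* **Search behavior**: in the antisaccade task, fixations outside the TA but
  within a Euclidean distance of `1.5 * L_TA` of the TA center (with `L_TA`
  the TA edge length) mark difficulty localizing the mirror position; runs
  of at least two consecutive marked fixations form search events, counted
  (`N_Search`), timed (`T_Search`, the summed member-fixation durations) and
  flagged (`B_Search`).
* **Gaze entropies**: the screen is tiled by a regular grid — 3 x 2 cells
  for the prosaccade/delayed tasks (n = 6), 4 x 2 for the antisaccade task
  (n = 8); the published grid layout is not machine-readable, so an equal
  rectangle tiling is the declared default and the dimensions are
  configurable. With `p_i` the fixation proportion per cell, stationary gaze
  entropy is `SGE = -Σ p_i log2 p_i`; with `p(j|i)` the first-order Markov
  transition probabilities of the fixation sequence, transition entropy is
  `GTE = -Σ_i p_i Σ_j p(j|i) log2 p(j|i)`, both normalized by
  `H_max = log2 n` into [0, 1] and with `0 log 0 = 0`. Self-transitions
  between consecutive fixations in the same cell are counted by default
  (configurable); `p_i` in the GTE formula is the same empirical stationary
  distribution as in SGE.

Boolean biomarkers are stored as 0/1 so that averaging yields incidences.
For the participant-level table, every metric is averaged over target side
and trial order while task and eccentricity are kept distinct, giving
`3 eccentricities x (number of applicable tasks)` columns per metric and 183
columns in all, named `<Task><Ecc>_<Metric>` (e.g. `P7_N_Fix`,
`A15_T_Search`). Missing trial values reduce the averaging denominator;
`L_TA_Fix` is averaged over completed trials only. Downstream models impute
remaining missing cells with training-fold medians (tree ensembles need
complete inputs; the median is robust and fold-local fitting avoids
leakage).

## Group statistics

Group comparisons use the pooled-variance two-sample t test
(`df = n1 + n2 - 2`; the pooled rather than Welch form is implied by the
constant df = 214 printed for all of the study's 216-participant
comparisons), the Pearson chi-square test without continuity correction
(which reproduces the printed sex statistic exactly), the Wilcoxon
Mann-Whitney U test (exact null distribution for untied samples up to n =
20 per group, tie-corrected normal approximation otherwise), the
Kruskal-Wallis test, and Bonferroni adjustment. The t test accepts printed
group summaries (mean, SD, n) directly so published tables can be recomputed
without raw data.

Variable filtering for the classifier retains feature columns whose
two-sided Mann-Whitney p-value is below 0.05 — the study states
"significantly different" without a number, and 0.05 is its stated
significance level; the alpha is configurable. Filtering is performed inside
each training fold by default (preventing selection leakage into held-out
folds); a single pre-CV filter can be requested for comparison.

## Classification

The classifier is gradient-boosted trees (xgboost) with binary logistic
loss and library-default hyperparameters, except that the exact greedy
split method is used: at cohort sizes (~200 rows) the histogram sketch buys
no speed and its bin-edge thresholds sit at the margin of the training data,
which generalizes poorly. Evaluation uses stratified 5-fold cross-validation
repeated 500 times by default (stratification is a design choice here — the
class split 122/94 is imbalanced and 43-sample folds otherwise risk skewed
class ratios). Within each fold: filter variables on the training portion,
impute medians, fit, score the held-out portion. Held-out scores are pooled
per repeat into one AUC/accuracy/sensitivity/specificity/precision/F1 set
(pooling stabilizes AUC relative to per-fold averaging at 43-sample folds);
the aggregate report gives means with percentile (2.5/97.5) 95% CIs across
repeats. AUC uses the rank (Mann-Whitney) formulation with ties counting
one half; confusion-matrix metrics use a 0.5 threshold with ADHD as the
positive class. Runs are deterministic given the base seed: fold draws and
per-fit tree seeds derive from (seed, repeat, fold). Variable importance is
the split gain summed per variable over all trees and averaged over fits.

## The synthetic cohort generator

No recordings were deposited with the study, so the package ships a
generator that synthesizes raw gaze streams with known ground truth. Each
trial is planned as a sequence of intended fixations honoring the task
timeline — central fixation, phenotype-driven excursions (unrelated-area
fixations, intrusive saccades, wrong-period target fixations), a
latency-delayed response saccade with optional direction errors and search
fixations around the target, and completion (or wandering until timeout) —
then sampled at the configured rate. Saccades follow a minimum-jerk position
profile scaled so the peak velocity matches the phenotype (realistic enough
for the I-VT detector without modeling oculomotor dynamics); the pupil
signal is a baseline plus slow sinusoidal drift (amplitude set so its SD
equals the phenotype's fluctuation parameter), white noise, occasional step
artifacts that exercise the MAD filter, and blink-like validity gaps.

Two presets encode the directional group contrasts reported for ADHD
vs. typically developing children: the ADHD-like phenotype has longer and
more variable saccade latency (350 +/- 80 vs 200 +/- 40 ms), more direction
errors (0.45 vs 0.10 per antisaccade trial), more search behavior (0.55 vs
0.15, ~3 vs ~2 annulus fixations), more unrelated-area fixations (rate 1.5
vs 0.3 per trial), more intrusive saccades (0.50 vs 0.10) and wrong-period
target fixations (0.50 vs 0.15), lower completion (0.85 vs 0.97), slower
saccades (peak 360 vs 450 deg/s), larger pupil fluctuation (SD 0.35 vs 0.15
mm), and more dispersed fixation targets. The study reports these directions
but not per-metric magnitudes (those sit in unavailable appendices), so the
preset values are the package's own one-time choices of plausible magnitudes
for children in this age range; they are *directional, not calibrated*, and
are deliberately separated clearly so that end-to-end pipeline failures are
attributable to code rather than to overlapping phenotypes. Gaze noise
defaults (3 and 6 px RMS, about 0.08-0.17 degrees) reflect research-grade
tracker precision, keeping the I-VT detector in its valid operating regime.

The default cohort layout mirrors the study enrollment: 122 TD and 94 ADHD
participants (43.5% ADHD) across three age groups, 12 trials per task. The
generator's default sampling rate is 250 Hz — a desk-scale setting chosen so
a 100-participant cohort synthesizes and extracts in about a minute; the
recording-grade 1200 Hz is available via `cohort_config()`.

**What passing tests show — and what they do not.** The generator emulates
the paradigm's timeline, geometry, kinematics and the directional group
contrasts, so end-to-end tests demonstrate that the pipeline recovers
planted effects with the right sign and that the classifier separates
separable phenotypes. Real recordings differ in ways the generator does not
model: oculomotor dynamics beyond minimum-jerk profiles, pursuit movements,
head-motion and calibration drift, luminance-driven pupil responses,
age-dependent developmental trajectories, and the actual effect sizes of the
clinical contrast. The published headline classification performance
(AUC 0.965) therefore cannot be — and is not — claimed to be reproduced by
synthetic data; the package instead validates chance-level behavior on pure
noise (a leakage check), near-perfect recovery on well-separated phenotypes,
and sign-correct recovery of every planted contrast.

## Numerical and testing choices

Problem sizes in the shipped checks are chosen to keep the full suite fast:
the end-to-end cohort uses 50 participants per group at 250 Hz with 50 CV
repeats, and the chance-level control averages five independent 216 x 183
noise tables with 10 repeats each (averaging over tables removes the
dataset-draw variance of a single chance AUC estimate). Entropy, U
statistic, AUC and MAD implementations are verified against brute-force
oracles to 1e-8 or better on hundreds of random instances. Degenerate inputs
follow explicit rules: empty event lists yield zero counts and missing
means; an empty pupil trace yields missing metrics with a warning;
zero-variance tests return a zero statistic (equal means) or a flagged
infinite statistic; a filter that retains nothing falls back to all columns
with a warning; single-class folds are redrawn.
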