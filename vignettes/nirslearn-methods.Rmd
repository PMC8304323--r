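---
title: "Decoding memory encoding and retrieval from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding memory encoding and retrieval from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirslearn)
```

## The problem

During a structured visuospatial learning task, the brain is at any moment
either *encoding* new information or *retrieving* it. `nirslearn`
implements a complete, testable pipeline that decodes these two states from
functional near-infrared spectroscopy (fNIRS) recordings acquired while
participants learn a motor sequence in a virtual environment, with half of
the cohort trained under simulated stressors (alarms, fires, smoke) and the
other half under normal conditions.

The pipeline has five stages, each an independently tested module:

1. **Session simulation** — protocol-faithful raw two-wavelength intensity
   recordings with known ground truth;
2. **Preprocessing** — raw intensity to oxygenated/deoxygenated/total
   hemoglobin concentration change (ΔHbO/ΔHbR/ΔHbT) per channel;
3. **Feature extraction** — a 651-dimensional windowed representation per
   labeled trial;
4. **Model selection** — 11 classifier families × feature-fraction sweep
   with randomized hyperparameter search, and a 3 × 3 condition-group
   transfer matrix;
5. **ROI importance** — noise-replacement permutation importance aggregated
   onto six cortical regions of interest.

## The montage

Eight sources and eight detectors form 21 measurement channels over six
regions of interest (ROIs): left and right dorsolateral prefrontal cortex
(LDLPFC, RDLPFC), medial prefrontal cortex (MPFC), left and right premotor
cortex (LPM, RPM), and the supplementary motor area (SMA). The exact
channel-to-ROI assignment is configuration, not code: the packaged default
(`default_layout()`; 4/4/3/4/4/2 channels per ROI in the order above) can
be replaced by any CSV with columns `channel,source,detector,roi`. All
feature indices derive deterministically from the layout's canonical 1..21
channel order.

## The session generator

Real recordings from the study this design follows are not publicly
deposited, so the generator is a first-class module: it defines the study
conditions under which every downstream claim is tested.

**Protocol.** Each simulated session has 3 familiarization trials, 8
training trials (each an error with probability `training_error_prob`,
default 0.2; an error inserts an extra familiarization trial), a 120 s
consolidation buffer, and 8 evaluation trials of which exactly 4 carry the
stressor condition (S) and 4 the normal condition (N), in seeded
counterbalanced order. Task trials last 20–60 s (uniform); the 20 s floor
guarantees every trial contains at least one 15 s analysis window. The
buffer length is a design choice (the protocol's source does not state
one), as is the 2 s inter-trial gap.

**Signal model.** Each ROI receives a boxcar neural drive with amplitude
(in µM ΔHbO equivalents) determined by the trial's state — encoding for
familiarization/training, retrieval for evaluation, a low "rest" level
(0.1 µM) for the buffer — and its condition. The drive is convolved with a
canonical double-gamma hemodynamic response (peak 6 s, undershoot 16 s,
peak:undershoot 6:1, unit gain on sustained drive). ΔHbR is coupled as
−ΔHbO/3, the conventional ratio. Stress recruits the prefrontal ROIs:
condition S multiplies PFC amplitudes by `stress_gain` (default 1.3) and
adds a tonic 0.2 µM PFC shift. Per-channel evoked gain varies ±15%.

**Nuisance structure**, added in optical density after the Beer–Lambert
forward projection: cardiac (≈1.1 Hz), respiratory (≈0.3 Hz) and Mayer
(≈0.1 Hz) sinusoids with per-channel random phase; a linear drift of
random sign (3 × 10⁻⁴ OD/s scale); white measurement noise (0.005 OD);
and motion artifacts at 0.5 events/min, of which 30% are persistent
baseline steps and the rest exponentially decaying spikes (τ = 0.5 s).
Intensities are `I = I₀ · exp(−OD)`, strictly positive by construction.

Three presets fix the activation topography:

* `"default"` — overlapping but distinct encoding/retrieval maps across all
  six ROIs (encoding weighted to LDLPFC/MPFC, retrieval to RDLPFC/RPM),
  amplitudes 0.3–1.0 µM. These are typical task-evoked ΔHbO magnitudes for
  prefrontal cortex.
* `"strong"` — encoding confined to LDLPFC, retrieval to RDLPFC, 2 µM
  against a 0.1 µM background with reduced noise: the planted-signal
  scenario for end-to-end recovery checks.
* `"null"` — identical amplitudes for both states: no class signal, used to
  verify that the workflow does not hallucinate separability.

**What the generator does not emulate:** superficial/systemic physiology
shared across channels (scalp blood flow), channel-specific optode-coupling
dropouts, serial correlation of motion events with task difficulty, and
any behavioral/psychometric structure beyond the Bernoulli training-error
flag. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers what its own forward model plants — a necessary
correctness property — not that real recordings carry equally clean
signal.

## Preprocessing

The chain runs in a fixed order (attempting to reorder it is a
configuration error):

```
intensity → OD → low-pass 3 Hz → spline motion correction
          → wavelet despiking → band-pass 0.016–0.5 Hz → Beer–Lambert
```

**Optical density.** `OD = −ln(I / mean(I))` per channel and wavelength,
with the session mean as reference, so constant intensity maps to zero OD.
Natural log is used throughout, with extinction coefficients in matching
units.

**Filters.** Butterworth, 4th order, applied forward–backward (zero phase)
with reflective edge padding. The band-pass is realised as a cascade of
low-pass (0.5 Hz) and high-pass (0.016 Hz) stages — numerically safer than
a single band-pass design at a normalized low edge of 0.016/4.35, and with
measured responses: linear drift attenuated to 0.2% RMS, 0.1 Hz passed at
99.9%, 1.1 Hz attenuated to 4.8%.

**Motion correction.** Artifacts are detected on the differenced series: a
1 s moving dispersion must exceed 3.5 × its channel median *and* the local
jumps must clear an amplitude floor (10% of the channel's robust 1st–99th
percentile range). The floor is essential: purely relative thresholds fire
on clean low-noise signals, where even smooth hemodynamic transitions
dominate the dispersion statistics. Flagged stretches (minimum 0.5 s) have
a cubic smoothing-spline trend subtracted and are re-leveled together with
all subsequent samples, which removes both transient spikes and persistent
baseline steps while leaving artifact-free input bit-identical.

**Wavelet despiking.** A periodized orthonormal Daubechies-5 decomposition
(4 levels, reflective padding to a dyadic length) zeroes detail
coefficients whose magnitude exceeds a robust universal threshold
(MAD-based σ̂ · √(2 log n)), again with an amplitude floor of 10% of the
channel's standard deviation. Isolated spikes concentrate into few outlier
coefficients; the smooth hemodynamic content stays below threshold. The
filter bank is implemented in-package and its perfect-reconstruction and
energy-conservation properties are tested directly.

**Beer–Lambert inversion.** Per channel and time point the 2 × 2 system
`ΔOD(λ) = [ε_HbO(λ) ε_HbR(λ)] · [ΔHbO ΔHbR]ᵀ · d · DPF(λ)` is solved, and
ΔHbT = ΔHbO + ΔHbR. Defaults: wavelengths 760/850 nm with Prahl's compiled
extinction coefficients (1.4866/3.8437 and 2.5264/1.7986 per mM·cm),
DPF 6.0 at both wavelengths, source–detector distance 3 cm — conventional
continuous-wave adult-head values, exposed as configuration because the
hardware's own calibration is not public. On a noise-free simulated
session the full chain recovers the band-passed ground-truth ΔHbO with
under 3% relative RMSE (the tests require < 5%).

## Feature extraction

Each participant's full-session ΔHbO/ΔHbR/ΔHbT series are min–max scaled
to [0, 1] per channel and signal (constant series map to 0 with a
warning), then cut into 15 s windows stepping by 7.5 s (50% overlap)
within each trial; sample counts are floored at 8.7 Hz (130-sample
windows, 65-sample steps — a 60 s trial yields 7 windows) and the first
window starts exactly at trial onset.

Each window yields 441 temporal statistics — for every channel and signal:
mean, biased variance, maximum, minimum, non-excess kurtosis
(normal → 3), skewness, and trapezoidal area under the curve with
dt = 1/8.7 s — plus 210 HbO functional-connectivity features, the Pearson
correlations of all channel pairs in lexicographic order: 651 features in
a deterministic, layout-derived column order. Zero-variance windows define
kurtosis and skewness as 0; a zero-variance correlation member yields
r = 0 with a warning.

Only the **first** window of each labeled trial enters the classification
table, capturing the participant's initial state in the trial.
Familiarization trials and errored training trials (plus their inserted
familiarization trials) are labeled *encoding*; evaluation trials are
*retrieval*; successful training trials and the buffer are excluded.

## Model selection

Whole participants are held out: 5 test participants (26 train with the
default 31), stratified by stress/control group, so no participant's
trials cross the split. Feature selection runs on the training rows only:
first a correlated-feature dropout (|r| > 0.95 removes the later feature
of a pair; on uncorrelated features it is a pass-through), then one-way
ANOVA F ranking of every surviving feature against the class label — for
two classes F equals the squared pooled t statistic, which the tests
verify to 10⁻¹⁰. The best N% of features (round(n · N/100), minimum 1;
13 features at 2% of 651) feed each of 11 classifier families: LR, KNN,
SVM, GB, ET, DT, RF, NB, AB, QDA, GP. Established implementations stand
behind the uniform interface (glmnet, class, e1071, xgboost, ranger,
rpart, MASS, kernlab); AdaBoost is implemented in-package as SAMME over
depth-limited rpart learners. Each family's hyperparameters are drawn 50
times (configurable) from a documented search space and scored by 5-fold
cross-validated F1 with retrieval as the positive class; QDA's space is
empty, so its "search" is a single fit.

Two choices deserve justification:

* **CV folds are grouped by participant.** Plain row-wise folds would let
  a participant's trials appear in both a training and validation fold,
  inflating CV scores through within-participant correlation. Grouped
  folds are the conservative reading of "5-fold".
* **The N and S transfer models reuse the SN-derived feature subset** by
  default (`rerank = TRUE` re-derives per group). Reuse matches the
  workflow in which the best algorithm and fraction are fixed on Group SN
  before being trained on the narrower groups.

The full sweep is 11 algorithms × 100 fractions = 1100 tuned models. The
packaged acceptance runs use a reduced grid (5 fractions, 10 search
iterations) so a complete study — simulation through transfer matrix —
finishes in minutes on a single core; the leaderboard records its
dimensions either way. Leaderboard ties break by higher F1, then higher
accuracy, then smaller fraction.

The transfer matrix trains one model per condition group (SN = all rows,
N = no-stress rows, S = stress rows) and evaluates each on each group's
test rows: 9 cells probing whether a model trained under one environmental
condition survives a change of condition.

## ROI importance

"Replacement by noise" is read as marginal-matched Gaussian replacement:
each feature column of the test rows is replaced by `N(mean, sd)` draws
matched to that column, the model is re-scored, and importance is the mean
accuracy drop over R repeats (default 10; within-column shuffling is
available as `noise = "shuffle"` since the phrase is nonstandard).
Importances are floored at 0, temporal features credit their channel's
ROI, connectivity features split 50/50 between their two channels' ROIs
(configurable; a same-ROI pair contributes fully), and each map is
normalized to sum to 1. Aggregation conserves the floored importance total
exactly, which is tested to 10⁻¹².

Single-feature replacement is known to understate the importance of
strongly correlated features: a saturated model over redundant features
can show zero drop everywhere. The recovery checks therefore run at a
realistic sub-ceiling signal-to-noise ratio (held-out accuracy ≈ 0.85–0.95,
the regime this method operates in on real data), where the planted ROI
tops its matched train–test cell in ≥ 9 of 10 seeded studies.

## Numerical and degenerate-input conventions

* All randomness flows through explicit seeds; identical seeds give
  bit-identical schedules, recordings, splits, tuned hyperparameters and
  importances. Sub-seeds are derived, never reused across stages.
* Filters and the wavelet transform use reflective padding; filter edges
  are validated against Nyquist.
* 0/0 conventions: ANOVA F = 0 for a feature constant everywhere;
  precision/recall = 0 when their denominators vanish (hence F1 = 0);
  an all-negative importance map normalizes to all zeros.
* A trial shorter than one window, a non-positive intensity, a singular
  extinction matrix, an unknown algorithm id and a single-class ANOVA all
  raise immediate, named errors.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run complete studies at sizes
chosen to exercise the full workflow while staying lightweight: the
end-to-end studies use 31 participants (26 train / 5 test, the design's
cohort size), the reduced sweep uses 5 feature fractions × 11 algorithms
at 10 search iterations, and the planted-ROI recovery repeats a compact
8-participant study over 10 seeds. All statistical oracles (closed forms,
naive-loop reimplementations, t² identities, Poisson and binomial bands)
run at small n in milliseconds.

## Known limitations

* The channel → ROI assignment is a packaged default, not the instrument's
  ground truth; analyses of real recordings should supply their own layout
  file.
* The generator's stress model (PFC gain + tonic shift) is a controllable
  knob, not a validated physiological model; transfer-matrix asymmetries
  on synthetic data follow from it by construction.
* Single-feature noise-replacement importance underestimates redundant
  feature groups; ROI maps should be read as relative, not absolute,
  attributions.
* No short-separation regression or systemic-physiology removal is
  implemented; superficial contamination in real data would pass through
  the chain.
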