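---
title: "Methods: mapping ON/OFF motor fluctuations from waist-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping ON/OFF motor fluctuations from waist-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with Parkinson's disease on long-term dopaminergic medication
alternate between ON phases (medication working, fluent movement) and OFF
phases (symptoms re-emerging, slow and effortful movement). Knowing *when*
each patient is ON or OFF over a day is key to adjusting therapy, but
self-report diaries are burdensome and unreliable. This package implements a
pipeline that maps ON/OFF state over time from a single waist-worn triaxial
accelerometer, using walking — a frequent, spontaneous behavior — as the
probe activity.

## Pipeline model

The pipeline has four stages, each exposed as ordinary R functions.

### 1. Walking detection

The raw signal (typically 200 Hz) is low-pass filtered and decimated to the
40 Hz analysis rate (`resample_to_analysis_rate()`), then cut into
non-overlapping 3.2 s windows of exactly 128 samples
(`windowing_config()`, `segment_windows()`). Each window is summarized by
two features: the spectral power of the mean-removed signal, summed over the
three axes, in the 0.1–3 Hz band and in the 0.1–10 Hz band
(`band_power()`, `compute_phase1_features()`). These two bands were
originally chosen by a ReliefF ranking over all 19,900 band candidates on a
0.1 Hz grid up to 20 Hz; both the ReliefF ranking (`relieff_rank()`,
`enumerate_band_candidates()`) and an AUROC-based per-band search
(`auc_band_search()`) are included so the selection step is reproducible.
A support vector machine with an RBF kernel, trained on labeled windows with
a stratified grid search over cost and kernel width
(`train_walking_model()`), classifies each window as walking or not.
Maximal runs of walking windows form *walking episodes*
(`episodes_from_labels()`).

### 2. Stride segmentation

Within each episode the first and last window are discarded as gait
initiation/termination transients (`trim_episode_boundaries()`). Initial
contacts — foot strikes — appear as relative maxima of the forward trunk
acceleration; they are detected with a minimum inter-peak separation of
0.35 s and a minimum topographic prominence of 0.05 g
(`detect_initial_contacts()`). A stride spans every second contact
(same-foot to same-foot, `build_strides()`); strides shorter than 0.5 s or
longer than 4 s are discarded as non-physiological.

### 3. Stride fluency and episode decisions

Each stride's *fluency* is the spectral power of its three-axis acceleration
in 0.1–10 Hz, normalized per unit time (`stride_fluency()`): fluent, vigorous
ON gait concentrates more power in this band than slow OFF gait. An episode's
decision value is the mean fluency of its strides after discarding the first
two and last two strides (`episode_fluency()`); episodes with fewer than five
strides emit no decision.

### 4. Patient-specific threshold

Fluency is not comparable across patients, so each patient gets a personal
threshold: a linear-kernel SVM on the one-dimensional fluency values of a
small calibration set with known ON/OFF labels (`fit_threshold()`). The
decision boundary `theta = rho / w` is the maximum-margin split of the
calibration fluencies; cost is selected by stratified cross-validation
(10 folds when each class has at least 10 patterns, otherwise 2), with ties
broken toward the largest cost (flatter, more regularized solutions change
nothing in 1-D separable data, and the largest tied cost gives the most
stable margin on the inner points). An episode is ON when its mean fluency
is strictly above the threshold, OFF when equal or lower
(`classify_motor_state()`).

## Validation protocol

`run_validation()` reproduces the evaluation design used on real cohorts:

- Decisions are compared to a gold-standard diary (`diary_timeline()`)
  recorded by a trained observer and confirmed by the patient.
- Five minutes of margin on each side of every ON/OFF transition are
  excluded (`transition_exclusion_mask()`) because the observer cannot
  timestamp state changes precisely; decisions in INTERMEDIATE or UNDEFINED
  diary intervals, straddling a transition, or outside the diary are dropped
  with an explicit reason (`label_decisions()`), and the bookkeeping identity
  `scored + dropped = total` is asserted in the tests.
- For each patient, a stratified random 20% of scored decisions calibrates
  the threshold and the remaining 80% are evaluated; this is repeated 30
  times (repeat *r* uses seed `base_seed + r`) and sensitivity, specificity,
  PPV and NPV — with **OFF as the positive class** — are averaged.
- Two variants are reported: all walking segments, and only segments with at
  least 10 strides (longer walks give more reliable fluency estimates).
- Patients with fewer than 2 scored decisions in either class cannot be
  calibrated and are reported as excluded.

## The synthetic cohort generator

Real recordings of medicated PD patients cannot be shipped, so
`simulate_patient()` / `cohort_plan()` / `run_study()` generate cohorts with
full ground truth. Defaults are chosen to emulate the validation setting and
are used unchanged as the study conditions of the test suite:

- **Sensor**: 200 Hz triaxial accelerometer, +1 g gravity on the vertical
  axis, white noise with SD 0.03 g, and a slow posture-drift sinusoid
  (0.02 g at 0.05 Hz) so rest is not spectrally empty.
- **Monitoring time**: uniform between 3 and 5 hours (clinic-visit scale);
  tests and the acceptance script fix 3 h per patient for runtime.
- **Motor phases**: alternating ON/OFF with lognormal durations (median
  1.5 h, log-SD 0.4, minimum 20 min), matching the 1–3 h scale of real motor
  phases; the first two phases are always one ON and one OFF in random order
  so both classes are represented; later phases are INTERMEDIATE with
  probability 0.1 to exercise the exclusion path.
- **Walking bouts**: a Poisson-like process at 30 bouts/hour with lognormal
  durations (median 40 s, clamped to 15–180 s) and at least 10 s of rest
  between bouts. The rate is set so that scored decisions arrive every few
  minutes, the output granularity the method achieves on real recordings.
- **Gait waveform**: each axis is a sum of the first three harmonics of the
  step frequency. The ON state uses cadence 1.9 Hz, the OFF state 1.5 Hz
  (clinically plausible fast/slow walking), and ON amplitudes are scaled by
  the *fluency contrast* (default 1.8), so ON band power exceeds OFF by the
  contrast squared. The forward-axis fundamental has phase zero, so its
  maxima are the ground-truth initial contacts recorded in `truth$contacts`.
- **Diary**: interior phase boundaries lag the true change by a 30 s
  reporting latency, emulating observer reaction time.
- **Cohort**: per-patient jitter (step frequencies ±0.1 Hz, amplitudes
  ×U(0.85, 1.15)) and deterministic per-patient seeds derived from the base
  seed; optionally some patients are "scarce OFF" (a single all-ON phase) to
  reproduce the patients excluded for lack of motor data in real cohorts.

What the simulator deliberately does **not** emulate: non-gait movement
(transfers, tremor, fidgeting), sensor orientation drift, turning and
stair-walking, freezing-of-gait episodes, gradual transitions between states,
and inter-stride variability beyond white noise. Walking/not-walking
separation is therefore easier than in free-living data, and absolute
validation numbers on synthetic cohorts should be read as upper bounds that
verify the pipeline's mechanics, not as clinical performance claims.

## Numerical choices

- **Band power** is computed from the rectangular-window periodogram of the
  mean-removed signal: `coef * |X_k|^2 / m^2` summed over DFT bins whose
  center frequency lies in the closed band, with `coef = 2` for interior
  bins (conjugate folding) and 1 at the Nyquist bin, summed over the three
  axes. With this normalization an amplitude-1 sinusoid at a bin center has
  power 0.5 g², disjoint bands partition the total mean-removed mean-square
  power (Parseval), and the tests verify both against a brute-force
  `O(m^2)` DFT oracle.
- **Anti-aliasing**: decimation to 40 Hz uses a zero-phase (forward-backward)
  8th-order Butterworth low-pass with cutoff at 0.7 × the target Nyquist
  (14 Hz). The 0.7 factor buys ≥ 40 dB attenuation at and above 20 Hz —
  an 8th-order filter at a higher cutoff does not reach 40 dB by the
  Nyquist — while the 0.1–10 Hz analysis bands sit well inside the flat
  passband.
- **SVM conventions**: both SVM surfaces use `e1071` (libsvm). The walking
  model stores its support vectors, coefficients and `rho`, and decision
  values are reconstructed explicitly so a model serialized to JSON (with an
  MD5 checksum) reproduces decisions exactly. Training is made
  order-invariant by canonically sorting the training rows before fitting.
  Class weights are inversely proportional to class frequencies.
- **AUROC** uses the rank (Wilcoxon) statistic with midranks for ties; the
  19,900-band search reuses one cumulative periodogram per stride, making
  the scan a `findInterval()` lookup per band.
- **Determinism**: every stochastic step takes an explicit seed, restores
  the caller's RNG state (`with_seed()`), and derives per-patient /
  per-repeat seeds arithmetically, so whole studies are bit-reproducible.

## Limitations

- The walking detector is trained on simulated development data by default
  (`train_default_walking_model()`); on real recordings it must be retrained
  on labeled windows.
- Thresholds require a calibration set with both states observed; patients
  who never record an OFF (or ON) phase cannot be calibrated — the
  validation protocol reports them as excluded rather than guessing.
- Fluency is a single scalar; states between ON and OFF (dyskinesia,
  intermediate states) are excluded from scoring, not modeled.
- All performance figures produced by this package's tests and acceptance
  script are computed on synthetic cohorts; see the test suite for the
  exact cohort definitions (15 patients, 3 h each, fluency contrast 1.8,
  with a contrast-1.0 chance control).
```{r}
# A minimal end-to-end run (see README for a worked example with output):
library(onoffgait)
cfg <- default_run_config(seed = 1)
model <- train_default_walking_model(seed = 1, cfg)
plan <- cohort_plan(3, sched = schedule_params(total_duration_s = 3600),
                    base_seed = 1)
study <- run_study(plan, model = model, cfg = cfg)
print(study$report)
```
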