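---
title: "Diagnosing color vision deficiency from frequency-tagged EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing color vision deficiency from frequency-tagged EEG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssvepcvd)
```

## The diagnostic paradigm

A subject sits before a display showing two Ishihara plates, each above a
square flickering at a distinct frequency (15 Hz or 18 Hz), and is asked a
question such as "which one is number 2?". Looking at a flickering square
entrains a steady-state visual evoked potential (SSVEP) at that flicker
frequency, strongest over occipital cortex (O1/O2), so the attended plate
can be read out of the EEG spectrum without any overt response. Six
sessions of ten 10-s trials each present plate pairs chosen so that a
red–green color-deficient observer reports the *non-target* plate every
time — either because the target digit is invisible to them, or because
the non-target is a hidden-digit plate that only they can see. Sessions 2,
4 and 6 use hidden-digit non-targets; the count of hidden-digit plates
"recognised" (i.e. attended) grades severity, since recognising more
hidden digits indicates a more severe deficiency.

`default_session_plans()` encodes the six questions ("2", "45", "5", "5",
"5", "2"), the hidden-digit placement, and the plate-to-frequency
assignment. The assignment is a display-layout fact that the paradigm
itself does not fix; the package's convention is that the target plate's
square flickers at 15 Hz in odd and 18 Hz in even sessions, so that both
frequencies serve as target and as non-target — which is what lets the
analysis report results per stimulation frequency. The column is plain
data and can be overridden for other layouts.

## The synthetic cohort generator

The study's recordings are not publicly deposited, so the package ships a
generator that reproduces the statistical structure the analysis relies
on, and every downstream stage is tested against it. Per channel, a
stimulation trial is

    x(t) = Σ_h a_ch · d^(h−1) · sin(2π h f t + φ_h)      (SSVEP, harmonics h = 1..3)
         + a_α · sin(2π·10·t + φ_α)                      (10 Hz non-target peak)
         + σ · n_1/f(t)                                  (1/f background)
         + a_line · sin(2π·60·t)                         (line noise)
         + sparse blink-like transients,

with rest epochs containing everything but the SSVEP term. The defaults
are fixed once and used everywhere, chosen as representative of
occipital SSVEP recordings:

* `ssvep_amp` = 2.5 µV at O1/O2, 1.5 µV at Pz, 1.0 µV at Cz — a few-µV
  entrained response with the occipital-dominant topography
  (O1 ≈ O2 > Pz > Cz); harmonic amplitudes decay geometrically
  (`harmonic_decay = 0.5`).
* `alpha_amp` = 3 µV at 10 Hz: display refresh effects and idling alpha
  produce a reliable ~10 Hz peak regardless of the tagged frequency. It is
  modelled as an additive tone because the observable being reproduced is
  a 10 Hz PSD peak, not the display hardware that causes it.
* `noise_scale` = 5 µV RMS of 1/f-shaped background (spectral exponent 1,
  the standard EEG background model), generated by spectral shaping of
  white noise.
* `line_amp` = 1 µV at 60 Hz; `artifact_rate` = 0.5/min transients of
  400 µV peak and 0.2 s width, with a random per-channel gradient (a
  spatially uniform transient would be silently removed by the average
  reference, which real blinks are not).

Two modelling decisions deserve explanation:

**SSVEP phase is locked to the stimulus within a session.** The SSVEP
phases `φ_h` are drawn once per (subject, session) and shared by that
session's ten trials, while alpha phase, background noise and artifacts
are drawn fresh per trial. SSVEPs are by definition phase-locked to the
driving stimulus; this is the premise that makes time-domain trial
averaging improve SNR (incoherent noise shrinks ≈ √10-fold over ten
trials while the evoked signal is preserved). Had the phase been
re-drawn per trial, averaging would cancel the signal itself and the
averaging step of the pipeline would be pointless.

**Behavioral choice model.** With probability `lapse_rate` a session's
choice is a uniform guess. Otherwise a normal-vision subject attends the
target plate; a CVD subject attends the expected CVD plate — in
hidden-digit sessions the hidden (non-target) plate with probability
`severity`, else the target; in the remaining sessions the non-target.
Marginally a non-lapsing subject attends its condition-expected plate with
probability 1 − lapse/2. Session 5 is sometimes described as a possible
severity indicator, but no rule for it is defined anywhere; severity here
is driven only by the hidden-digit sessions 2/4/6, and the severity score
counts only those.

What the generator does **not** emulate: volume-conducted channel
correlations (channels get independent noise), non-stationarity and
drowsiness drifts, eye-movement and EMG spectra, inter-subject amplitude
variability, or photometric display detail. Passing tests on this
generator therefore show that the pipeline correctly recovers the
structure the paradigm assumes — not that it would attain the same
accuracy on any particular real cohort.

## Preprocessing chain

`preprocess_recording()` applies, in order: a 4th-order Butterworth
band-pass 5–30 Hz; a 60 Hz notch; a second band-pass 5–50 Hz; common
average reference; trigger-based segmentation into 10-s trials;
±100 µV amplitude rejection; and per-session averaging of the surviving
trials. Choices made where the procedure leaves room:

* **Zero-phase filtering by default.** Filters are applied
  forward–backward (`signal::filtfilt`), which doubles the effective
  order but has no group delay, so epoch boundaries are not smeared.
  `zero_phase = FALSE` gives the strict causal single-pass variant for
  anyone replicating an acquisition-side filter.
* **Notch Q = 30.** Narrow enough to leave 50–59 Hz content (which the
  second band-pass stage still admits) untouched; a pure 60 Hz tone is
  attenuated by far more than 20 dB.
* **Both band-pass stages are kept** even though the 5–50 Hz stage is
  nearly a no-op after 5–30 Hz: the chain mirrors a two-stage acquisition
  setup faithfully, and `single_bpf = TRUE` collapses it when only the
  effect matters.
* **Amplitude rejection is the artifact path.** ICA-based artifact
  removal requires manual component selection by visual inspection and is
  not reproducible as code; the amplitude criterion (reject a trial iff
  any channel exceeds ±100 µV at any sample, boundary inclusive) is
  implemented as the sole rejection rule. Note that zero-phase 5–30 Hz
  filtering attenuates a 0.2 s, 400 µV transient roughly five-fold, so at
  default generator settings most transients duck under the threshold
  after filtering — rejection earns its keep on rawer data, and its
  semantics are tested on unfiltered segments.
* **Epoch bookkeeping.** Sample indices are 0-based half-open throughout.
  Epochs within ±2 samples of 10 s are trimmed/zero-padded (trigger edges
  jitter by a sample on real hardware); shorter epochs are skipped with a
  warning. Trigger glitches are never silently smoothed —
  `min_epoch_samples` exists for explicit cleaning. Consecutive blocks of
  `n_trials_per_session` stimulation epochs map to sessions 1..6,
  matching the sequential protocol. A session whose trials are all
  rejected is reported as unusable rather than silently dropped.

## Spectral and CCA features

`welch_psd()` averages Hann-windowed, mean-subtracted 250-sample segment
periodograms at 50% overlap: 19 segments per 2,500-sample trial and a
1 Hz bin spacing. The periodogram is density-scaled — divide by
`fs · Σw²` and double the interior one-sided bins — so values are
genuinely µV²/Hz and satisfy Parseval's relation; `scaling = "raw"`
reproduces the unscaled |X(k)|²/M textbook form for comparison. Each
segment is mean-subtracted before windowing to keep DC leakage out of the
low bins.

`cca_max_correlation()` computes, per channel, the maximum canonical
correlation against the H = 3 harmonic sine/cosine bank. The feature
count (8 CCA features = 4 channels × 2 frequencies) dictates a
*per-channel* statistic, and for a single channel the maximum canonical
correlation reduces exactly to the multiple correlation coefficient of
the channel on the reference rows; it is computed by reference-side
normal equations with a relative ridge of 1e-10 on the Gram matrix
(a 1-D x makes the full generalized eigenproblem unnecessary). A
multichannel mode (orthonormal-basis SVD) is available for exploration.
Tests cross-check both routes against `stats::cancor` and a brute-force
weight-vector optimization.

**Which segments feed the features** is genuinely underdetermined: "16
features per subject" could come from one grand-average segment or from
session groups. The package computes the frequency-f-indexed features
from the average of the sessions whose *target* frequency is f, for a
structural reason: under the alternating plate-frequency assignment both
conditions attend 15 Hz in three sessions and 18 Hz in the other three,
so a grand average over all six sessions is nearly identical between
groups and carries no diagnostic signal. Grouping by target frequency
makes normal subjects (who attend the target) score high at f on group f
and CVD subjects (who attend the non-target) score low there — all 16
features point the same way. A `per_frequency` mode emits the two 8-value
matrices (4 channels × {PSD, CCA} at the group's own target) separately,
mirroring analyses reported per stimulation frequency.

The PSD-ratio statistic `psd_group_ratio()` — mean normal-group PSD over
a band divided by the CVD-group mean — reproduces the expected band
asymmetry on simulated cohorts: above 1 in 14–16 Hz and below 1 in
17–19 Hz for 15 Hz-target sessions.

## Rule-based diagnosis

`detect_attended_frequency()` scores each candidate as the channel-mean
PSD, CCA, or fused statistic (mean of per-method min–max-normalized
scores, a simple order-preserving fusion) and takes the argmax. An exact
tie resolves to the session's target frequency: a stated rule beats a
platform-dependent argmax, and biasing ties toward "normal" is the
conservative direction for a deficiency screen. All-constant segments
yield a flagged indeterminate result instead of an error.

The subject-level rule is the package's own construction (the per-session
paradigm defines expectations but no formal subject rule, its subject
call being delegated to the classifiers): with threshold 4, a subject is
called CVD at ≥ 4 of 6 CVD-expectation matches, normal at ≤ 2, and
indeterminate in the symmetric band between. The severity score counts
hidden-digit plates attended among sessions {2, 4, 6}, so it ranges 0–3.

## Classification stack

* **SMOTE** is authored in the package (convex interpolation toward one
  of the k nearest minority neighbors). With 5 minority subjects the
  textbook k = 5 is infeasible, so k defaults to `min(5, minority − 1)`.
  By default SMOTE runs *inside* each training fold (`fold_internal`),
  because balancing before the split leaks synthetic copies of test
  subjects into training; `smote_mode = "global"` reproduces the
  balance-first-then-CV order for comparison, and the two modes also
  embody the two possible sample definitions (16 subjects vs 22 balanced
  samples) for reported accuracies.
* **Standardization.** PSD features (µV²/Hz, ~1e-2 here) and CCA features
  ([0, 1]) differ by orders of magnitude, so features are z-scored with
  training-fold statistics before KNN and SVM, which are distance- and
  margin-based; the decision tree is scale-invariant and takes raw
  features.
* **Decision tree**: axis-aligned binary splits maximizing information
  gain under Shannon entropy (−Σ p log₂ p), midpoint thresholds,
  deterministic lowest-index/lowest-threshold tie-breaks, depth cap 5, no
  pruning, majority leaves.
* **KNN**: Euclidean distance √Σ(xᵢ−yᵢ)², k = 5, class ties broken by
  the smaller summed distance, then lexicographically.
* **SVM**: polynomial kernel exactly of the form (1 + x·x′)^d with
  d = 3, C = 1; the quadratic program is solved by `e1071::svm`
  (`gamma = 1`, `coef0 = 1`, internal scaling off) — solver internals are
  not the contribution, the kernel form is.
* **Evaluation**: stratified folds (per-class round-robin after a
  shuffled permutation, so fold sizes differ by at most one per class),
  accuracy as the percentage of correctly assigned responses, a pooled
  confusion matrix with CVD as the positive class, and
  precision/recall/specificity/F1 with zero-denominator cases reported
  as 0 and flagged. With 16 subjects and 5 folds, each fold holds 1 CVD
  and 2–3 normal subjects.

## Numerical and degenerate-input conventions

Constant signals make correlation undefined and raise an error; rank-
deficient reference Gram matrices are ridge-solved with a warning.
`psd_feature()` reads the nearest bin with ties toward the lower
frequency (exact bins at default parameters). Harmonics at or above
Nyquist are refused in references (error naming the harmonic) and
skipped in the generator. Zero-length recordings epoch to an empty
table, not an error. All stochastic functions take explicit seeds and
restore the caller's RNG state.

## Problem sizes and what the checks cover

The test suite exercises the full study geometry — 11 + 5 subjects, 6
sessions × 10 trials at 250 Hz — once, for the end-to-end checks
(feature-count accounting, paradigm recovery, classifier bounds), and
uses 3-trial sessions and small Monte-Carlo ladders (30–100 draws) for
unit-level properties; these sizes are the package's chosen trade-off
between statistical resolution and a test run of under a minute.
`scripts/acceptance.R` re-runs the full-scale computation from scratch at
any seed.

## Known limitations

* The generator's independence assumptions (white-across-channels noise,
  no drowsiness or habituation) make the synthetic classification task
  easier than a real cohort's; the reported 95–100% cross-validated
  accuracies on synthetic cohorts are upper bounds of pipeline
  correctness, not clinical performance claims.
* The paradigm does not separate protan from deutan deficiencies, and the
  severity score is a 0–3 ordinal, not a calibrated severity scale.
* `n = 16` subjects with 5-fold CV yields noisy per-fold accuracies
  (granularity ~33%); the standard deviation across folds should be read
  accordingly.
* EDF/BDF input and live streaming are out of scope; recordings enter as
  OpenBCI-GUI-style text or the native CSV + JSON pair.
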