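---
title: "Decoding short mental-task trials from hybrid EEG-NIRS recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding short mental-task trials from hybrid EEG-NIRS recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbci)
```

## The problem

A hybrid brain-computer interface (hBCI) combines electrical (EEG) and
hemodynamic (NIRS) views of the same mental activity. EEG reacts within
milliseconds but is noisy and artifact-prone; the NIRS oxygenation response
is robust but develops over seconds. Because the information transfer rate
(ITR, bits/min) of a BCI falls quickly as the per-decision time grows,
the design question this package addresses is whether *short* (5 s) trials
of intuitive mental tasks — mental arithmetic (MA) and word chain (WC),
contrasted against relaxed baseline (BL) — can be decoded accurately enough
that fusing EEG and NIRS beats either modality alone.

The package implements the full analysis as reusable, tested components:
a synthetic-recording generator (there is no public dataset for this
paradigm, so the generator *is* the study bed), the preprocessing chain,
feature extraction, classification, and evaluation with ITR reporting.

## Paradigm and synthetic data

A session consists of 30 trials (10 per class, seeded random order). Each
trial is a 2-s visual instruction, a 5-s task, and a rest drawn uniformly
from 13–15 s; a pre/post rest flanks the session (default 60 s — reports of
this paradigm disagree between 1 min and 15 s, so it is configurable and
nothing downstream depends on it). Three sessions are recorded per subject.

`simulate_dataset()` emulates, per session:

* **EEG (10 frontal channels, default 200 Hz)** — pink (1/f) background plus
  three band-limited oscillation sources (theta 4–8, alpha 8–13, beta
  13–30 Hz) mixed into the channels with fixed weights. During a task
  window the oscillation envelope is multiplied by
  `(1 - erd_depth) * (1 + ers_gain)` with 0.5-s cosine ramps: MA deepens
  alpha (0.5) and beta (0.3) desynchronization and adds theta
  synchronization (0.4); WC desynchronizes broadly (alpha 0.45, beta 0.35,
  theta 0.2); BL does nothing. A per-trial log-normal gain
  (`trial_gain_sd = 0.25`) models excitability fluctuations.
* **EOG** — Poisson blinks (smooth ~120 µV pulses) and saccade steps, leaked
  into the frontal channels through a fixed propagation map.
* **NIRS (9 prefrontal channels, 12.5 Hz)** — per trial, HbO is the class-
  and channel-specific peak amplitude (MA ≈ 0.85 µmol/L medially, WC ≈
  0.80 µmol/L left-lateralized) times a canonical double-gamma response
  (peak 6 s, undershoot 16 s) convolved with the 5-s task boxcar; HbR is a
  0.3-scaled, 0.5-s-delayed negative copy. Systemic noise — Mayer wave
  (0.1 Hz), respiration (0.3 Hz), cardiac (1.1 Hz) — is *shared across
  channels* with mild per-channel gain spread, plus channel-independent slow
  drift and sensor noise. Sharing the systemic components matters: if each
  channel drew its own Mayer wave, a multichannel classifier would average
  it away and the problem would become unrealistically easy.
* **Session drift** (`session_drift_sd = 0.15`) — log-normal per-session
  scaling of effect amplitudes and channel gains, so chronological
  (pseudo-online) evaluation is harder than shuffled cross-validation, as
  observed in practice.

Effect sizes and noise amplitudes were chosen once so that the default
conditions land in the accuracy regime reported for this paradigm
(group-mean offline accuracies in the high 70s to high 80s percent, hybrid
above both unimodal classifiers); they are deliberate package defaults, not
fitted quantities. Everything is seeded: identical configuration and seed
give bit-identical datasets, with per-session streams derived from the
master seed.

What the generator does **not** emulate: volume conduction from a head
model, non-stationary artifact spectra, motion artifacts, short-separation
channel physiology, or the initial dip of the hemodynamic response. Passing
the end-to-end tests therefore shows the pipeline recovers the *intended*
statistical structure, not that it is robust to every pathology of real
recordings.

## Preprocessing

* EEG: 1–40 Hz band-pass (4th-order Butterworth, forward–backward), optional
  EOG correction, decimation to 100 Hz behind a zero-phase FIR anti-alias
  filter (cutoff 0.8 × the target Nyquist).
* EOG correction: `regression` subtracts the least-squares projection onto
  the EOG channels; `ica` runs a deterministic fixed-point ICA (tanh
  contrast, identity initialization in whitened space) and zeroes components
  correlating with any EOG channel above |r| = 0.7; `none` is supported
  because the correction does not change the decoding outcome materially.
* NIRS: optical density (when simulated) is inverted through the modified
  Beer-Lambert law — a 2 × 2 linear solve per channel and sample using
  760/850 nm extinction coefficients, 3 cm separation, DPF 6.0 — then
  band-passed 0.01–0.2 Hz with a 6-pole zero-phase Butterworth to suppress
  drift, respiration and cardiac components (the Mayer wave at 0.1 Hz is
  inside the passband and survives; that is the dominant residual noise).
  A 12-pole version of this filter is numerically unstable at a normalized
  low edge of 0.0016, which is why "order 6" here means six poles.
* Epoching: −5 to 5 s around task onset on the sample grid `k/fs` that
  contains t = 0 exactly, with `round(10 fs) + 1` samples (1001 at 100 Hz,
  126 at 12.5 Hz; at 12.5 Hz the grid cannot contain both ±5 s and 0, so
  the window is [−4.96, 5.04] s). Baseline correction subtracts the
  per-trial, per-channel mean over −5 to −2 s — before the instruction, on
  the assumption that subjects may start working during it.

## Features

* **EEG**: filter-bank common spatial patterns. Each epoch is band-filtered
  (6-pole zero-phase Butterworth per band; this order keeps neighbouring
  default bands ≥ 20 dB apart after the double pass). Per band, trial
  covariances over the 0–5 s task window are trace-normalized, averaged per
  class, and jointly diagonalized via the whitened generalized eigenproblem;
  eigenvector signs are fixed (largest entry positive) for reproducibility,
  and a rank-deficient pooled covariance receives a `1e-9 · trace/d`
  diagonal load with a warning. Features are the log of the raw projected
  variance of the first and last three components — 3 bands × 6 components
  = 18 features. Trace normalization makes the filters exactly invariant to
  orthogonal channel mixings; a general invertible mixing changes the class
  trace ratio and is only approximately invariant, which is the price of
  the normalization's robustness to trial-amplitude outliers.
* **NIRS**: per chromophore, channel, and sub-window (0–2, 2–4, 4–5 s;
  half-open except the last, so they partition the task period exactly at
  12.5 Hz), the mean and the least-squares slope (mol/L/s) — 9 × 3 × 2 = 54
  features each for HbO and HbR. "Average slope" could also be read as the
  endpoint difference over the duration; both are implemented
  (`slope_method`), least squares is the default because it uses every
  sample.

## Classification

All classifiers are shrinkage LDA: `w = Σ̃⁻¹(μ₁ − μ₂)` with
`Σ̃ = (1 − λ) Σ̂ + λ ν I`, `ν = trace(Σ̂)/D`, and λ from the analytic
Ledoit-Wolf formula on the pooled within-class centered samples. The scaled
identity target is the default because an unscaled `λI` is not invariant to
the units of the features; a strict `target = "identity"` mode is provided
for fidelity to the usual textbook notation. Decision values are
`w·x − b` with the bias at the class-mean midpoint; an exact 0 resolves to
the second class of the pair, deterministically.

A property worth knowing: when the true covariance *equals* the shrinkage
target (spherical data), the Ledoit-Wolf oracle intensity is 1 — shrinking
fully onto the truth — regardless of the sample size, because both the
entry-variance numerator and the dispersion denominator are pure sampling
noise of the same order. λ → 0 with growing n only when the truth is
non-spherical. The test suite pins both behaviours.

The two-layer **meta classifier** fuses modalities: base sLDAs for EEG,
HbR, and HbO produce continuous decision values; a second sLDA is trained
on those values (input dimension 2 for HbR+HbO = "NIRS", 3 for
EEG+HbR+HbO = "hBCI"). The meta layer is trained on *out-of-fold* base
outputs from a deterministic stratified 5-fold inner split — training both
layers on resubstitution outputs (`mode = "naive"`, provided for
comparison) lets the meta layer inherit the base models' optimism. Base
models are refit on all training trials for deployment.

## Evaluation

* **Offline**: 10 × 5-fold stratified cross-validation; CSP filters and all
  classifier layers are refit inside every training fold, so no test trial
  ever influences a fitted model (the suite verifies that corrupting test
  labels changes no prediction).
* **Pseudo-online**: train on sessions 1–2, test on session 3 (`causal`,
  the default), or leave-one-session-out (`session_cv`). For a binary pair
  this trains on 20 and tests on 10 trials per class.
* **Learning curve**: stratified subsets of n trials per class from the
  training sessions, tested on the last session; with the full training set
  and one resample it reproduces the causal pseudo-online result exactly.
  `min_training_samples()` extracts the smallest n exceeding an accuracy
  target (the conventional effective-BCI threshold is 70%).
* **ITR**: `m (log₂N + P log₂P + (1−P) log₂((1−P)/(N−1)))` bits/min with
  `m = 60/trial_len_s`, `trial_len_s = 5` and `0·log₂0 ≡ 0` — the decision
  time is the task period only, which is how theoretical ITRs for this
  paradigm are quoted. ITR is convex in P on (0.5, 1], so the ITR of a
  group-mean accuracy is a lower bound on the group-mean ITR.
* **Chance level**: smallest k/n with an exact binomial tail below α under
  random guessing — 37/60 ≈ 61.7% for 60 trials at α = 0.05.
* **Statistics**: Friedman omnibus over subjects × modalities (a fully tied
  table is reported as statistic 0, p 1), pairwise exact Wilcoxon
  signed-rank (normal approximation with continuity correction above
  n = 25), Benjamini-Hochberg adjustment.
* **ERD/S maps**: Hann-tapered sliding-window spectra (default 5120 ms
  window, 80 ms step, zero-padding ratio 2), trial- and channel-averaged,
  in dB relative to the per-frequency *geometric* mean over the baseline
  interval — the geometric reference makes the baseline rows average to
  exactly 0 dB, so task-related changes read directly as dB deviations.

## Numerical and design choices

* Epoch grid, filter orders, tie-breaks, eigenvector signs: above.
* Inner meta folds are assigned round-robin within class, not randomly, so
  a fitted meta model is a pure function of its training data; outer CV
  folds are seeded-random and stratified.
* The pipeline order is filter → EOG-correct → decimate; it is configurable
  because the conventional order is not fixed in the literature.
* Degenerate inputs: an all-constant feature set yields ν = 0 and is
  flagged, falling back to the mean-difference direction; duplicated
  modalities in the meta layer are handled by shrinkage; fewer trials than
  inner folds reduces the fold count with a warning.

## Problem sizes

The test suite exercises the full pipeline at the default effect sizes with
EEG simulated directly at its 100 Hz analysis rate and short flanking
rests (the sampling rate and rest length are not effect parameters); ten
synthetic subjects (seeds 0–9) are evaluated with 2 × 5-fold offline CV
plus the causal pseudo-online split, and the same ten subjects with all
effects zeroed provide the null calibration. `scripts/acceptance.R` runs
ten subjects at the unreduced defaults (200 Hz EEG, 60-s rests, both class
pairs) with 2 × 5-fold offline CV and reports group-mean accuracies, ITRs
and the ITR reference points.

## Limitations

* The generator's realism is phenomenological; transfer of the reported
  accuracies to laboratory recordings is out of scope.
* Binary classification only (MA vs BL, WC vs BL): the three-class problem
  and MA vs WC are known not to separate well in this paradigm and are not
  implemented.
* No real-time loop: pseudo-online evaluation emulates chronology, not
  latency.
* File-format adapters (vendor EEG/NIRS formats) are not core; the plain
  text container written by `write_container()` is the interchange format.
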