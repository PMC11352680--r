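---
title: "Recognising taste states from facial sEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising taste states from facial sEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgtaste)
```

## The problem

When the tip of the tongue is stimulated electrically or thermally, people
report taste sensations — sour, salty, bitter, minty, the tingle of a
carbonated drink. Facial muscles (the depressors around the mouth, the
masseter, the parotid region) respond to these sensations, and their surface
electromyogram (sEMG) carries enough structure to tell the evoked states
apart. `emgtaste` implements the full analysis chain for this recognition
task: windowing of multichannel recordings, artifact removal, a
126-dimensional time/frequency feature set, and cross-validated
random-forest experiments. Because taste-stimulation sEMG corpora are not
publicly deposited, the package ships a synthetic-signal generator that
reproduces the statistical structure the analysis assumes, so every stage is
testable end to end without any download.

## The recording model

A trial is an `n_channels x T` matrix in microvolts: 6 channels, 8 s at
1000 Hz under the default protocol, labelled with one of six taste states
(`no`, `sr`, `sp`, `bt`, `mt`, `st`; a four-state subset serves the
electronic-vs-actual-tastant comparison). The generator writes each trial as
the sum of four components:

* **Muscle activity.** Stationary Gaussian noise shaped in the frequency
  domain: each one-sided DFT bin inside an analysis band receives an
  independent complex-Gaussian coefficient whose expected magnitude equals
  the taste's configured band level, so the mean window spectrum *is* the
  band profile. Energy concentrates below 100 Hz, reflecting the low-pass
  behaviour of circular surface electrodes. The default profiles peak near
  20–30 Hz at ~550 µV bin magnitude; together with drift and interference a
  raw trial spans several hundred µV, consistent with a ±2000 µV
  artifact-rejection threshold. Much weaker profiles would sit below the
  motion-artifact residual floor and leave the taste classes
  indistinguishable after filtering.
* **Baseline drift.** A degree-4 polynomial with i.i.d. Gaussian
  coefficients (default SD 300 µV) on a time axis normalised to [−1, 1].
  This is exactly the model class the detrender removes, which makes the
  detrend residual testable to numerical precision.
* **Powerline interference.** Common-mode sinusoids at 50 Hz and odd
  harmonics ((2k−1)·50 Hz with amplitude `powerline_amp`/k, default 20 µV
  and three components: 50, 150, 250 Hz), with a random phase per trial.
* **Motion artifact.** Band-limited 1–10 Hz Gaussian noise, default 20 µV
  RMS.

With probability `outlier_prob` a trial carries one high-amplitude
excursion: a 10 ms half-sine of 3000–6000 µV in one random channel,
confined to a single 1 s window. The burst is deliberately short: a longer
(e.g. 50 ms) burst concentrates its energy near 10 Hz and the high-pass
filter would attenuate it below the rejection threshold, defeating its
purpose of exercising the abnormal-amplitude rejection on exactly one
window.

**Block synthesis.** The stochastic components (muscle activity and motion
artifact) are generated in independent 1 s blocks aligned with the
downstream windowing grid. Drift and powerline span the whole trial but are
removed exactly (drift is in the detrender's model class; powerline
magnitudes are phase-invariant and notched per window), so the extracted
windows are statistically independent. This is a deliberate idealisation:
real recordings have cross-window correlation within a trial, which
window-level cross-validation would partially leak into test folds. The
`by_session` fold scheme exists for exactly that situation on real data;
passing tests on synthetic data therefore demonstrate the correctness of
the machinery, not the absence of leakage in real corpora.

**Participant heterogeneity.** Each participant carries a fixed
multiplicative log-normal perturbation of the band profiles,
`exp(h·z)` per band, shared across tastes — a participant-level spectral
gain. With `h = 0` participants are exchangeable; increasing `h` raises
within-class variance in pooled datasets, which is what drives the decline
of accuracy with participant-group size. The default `h = 0.15` represents
mild inter-individual variation; the grouping experiments in the test-suite
plant `h = 0.6` to make the decline unambiguous.

## Preprocessing

Per recording: slice into non-overlapping 1 s windows (a trailing partial
window is dropped), then per window:

1. **Polynomial detrend** (degree ≤ 4, least squares on a [−1, 1] axis with
   an orthogonal-polynomial basis). Any degree-≤4 trend is annihilated to
   < 1e−6 µV.
2. **Zero-phase Butterworth high-pass**, 4th order, 10 Hz cutoff. The
   filter is applied in the frequency domain: the window's DFT is
   multiplied by the squared magnitude response |H(f)|², which is exactly
   the net effect of a forward plus a reverse pass, with circular boundary
   treatment. Time-domain forward–backward filtering (with either
   zero-padding or odd reflection) rings at the window edges; the ringing
   amplitude depends on the powerline phase at the boundary, which is
   identical for every window of a trial and therefore imprints a spurious
   trial signature on the high-frequency bands. The spectral application
   has no edge transient at all and handles integer-bin sinusoids exactly;
   its effective gain is the closed form (f/f_c)^8 / (1 + (f/f_c)^8).
3. **Adaptive powerline notch.** For each multiple of 50 Hz up to 450 Hz,
   the mean magnitude within ±1 Hz of the harmonic is compared with the
   median magnitude of the ±2…±10 Hz flanks; if the centre exceeds twice
   the flank level (ratio configurable) the centre coefficients are rescaled
   to the flank magnitude, preserving phase. Harmonics that do not stand
   out are left untouched — the notch intensity adapts to the interference
   actually present.
4. **Abnormal-amplitude rejection.** A window is kept only if every channel
   stays within ±2000 µV. Rejection operates per window (whether the
   protocol intends per-window or per-trial rejection is not fixed; the
   threshold is a parameter and the partition of kept/dropped windows is
   reported with provenance).

The chain is idempotent on the interference it targets: re-running it on
the preprocessed output of a drift-plus-powerline recording changes
essentially nothing. It is not exactly idempotent on stochastic content —
each detrend pass re-projects broadband noise onto the degree-4 basis
(expected √(5/L) ≈ 7% of its RMS per pass), and re-applying |H|² rescales
passband bins by up to ~0.4% near 20 Hz; the tests bound this re-run change
instead of asserting exact fixed-point behaviour.

## Features

Per channel, 21 features; per 6-channel window, 126 values in channel-major
order (`ch1_F1 … ch6_F21`):

* **F1–F13, band averages**: mean one-sided DFT magnitude over nine 10 Hz
  bands (10–100 Hz) and four 100 Hz bands (100–500 Hz). With the default
  1 Hz bins these are the plain averages `F[n] = (1/10) Σ f(i)` over
  `i = 10n … 10(n+1)−1`, and the analogous 100-bin averages.
* **F14–F16, spectral moments**: the magnitude-weighted centroid FC, the
  second moment about zero (RMSF) and about the centroid (RVF), over bins
  1…L/2. The moment features are computed *as their defining equations are
  printed* — without a square root, although the names suggest one;
  `apply_root = TRUE` applies it. The DFT magnitude is left unnormalised:
  the moments are scale-invariant and the band averages only require
  internal consistency.
* **F17–F21, time domain**: RMS, zero-crossing count scaled by 1/10 (again
  as the defining equation prints it — the factor is kept for fidelity even
  though a per-second rate would need none), mean absolute value, kurtosis
  and skewness with the population (divisor L) standard deviation.

Degenerate windows (identically zero spectrum, or constant channels where
kurtosis and skewness are undefined) are excluded from the feature table
with a logged count rather than imputed — they cannot occur in realistic
data, and explicit exclusion is auditable.

## Evaluation experiments

All experiments use a random forest (default 100 trees, √D features per
split, unlimited depth) under stratified k-fold cross-validation (default
five folds at the window level, with `by_session` as the
leakage-safe alternative for real data), seeded and bitwise reproducible.
Accuracy is the mean over folds; confusion matrices are row-normalised
counts accumulated over test folds.

* `five_fold_cv()` — the headline protocol.
* `feature_sweep()` — shuffles the 21 feature *types* into a seeded random
  order and evaluates the first k types for k = 1…21 (each type contributes
  its column from every channel; the granularity follows the convention of
  counting feature types, not columns).
* `participant_grouping()` — evaluates every non-empty participant subset
  (2^P − 1 datasets; 255 for P = 8) and averages accuracy per subset size.
  Refuses P > 12.
* `scenario_compare()` — the same protocol side by side on two datasets
  sharing a label set, e.g. electronic versus actual tastants over the
  four-state set.

## What the tests do and do not show

The test suite checks (sizes chosen to keep the default run in minutes):

* closed-form DFT identities of the generator and the feature extractor;
* exact annihilation of the detrender's model class and the closed-form
  Butterworth gains;
* agreement of all 21 features with an independent brute-force
  transcription of their defining formulas to 1e−9 relative on 100 random
  windows;
* chance-level accuracy (±0.05 of 1/6 at N = 1200) when band profiles are
  identical across tastes, and > 0.95 accuracy when profiles are widely
  separated (contrast exponent 2);
* the grouping experiment's two regimes on 8 participants × 96 windows:
  with planted heterogeneity (h = 0.6) mean accuracy is non-increasing in
  subset size (±0.03 slack per step); with h = 0 the curve is flat
  (range < 0.05). The flatness check runs at raised class contrast
  (exponent 1.5) so that accuracy is near ceiling at every subset size —
  at moderate contrast a random forest is still on its learning curve at
  these sample sizes, and larger subsets would score higher for sample-size
  reasons alone, confounding the exchangeability property being tested.

Passing these tests shows the machinery is correct under the generator's
assumptions. It does not show that real facial sEMG satisfies those
assumptions: real signals are nonstationary within trials, electrode
placement varies between sessions, and within-trial correlation makes
window-level cross-validation optimistic. On real data, prefer
`fold_scheme = "by_session"` and treat window-level figures as upper
bounds.

## Numerical choices

* Polynomial fits use an orthogonal basis on [−1, 1]; degree is capped at 4.
* The notch threshold ratio defaults to 2.0 with ±1 Hz centre and ±2…10 Hz
  flanks; the flank statistic is a median so one neighbouring tone does not
  inflate the reference level.
* Harmonics are notched up to 450 Hz, below the 500 Hz Nyquist limit.
* All randomness flows from explicit integer seeds: per-trial seeds are
  derived deterministically from the dataset seed, participant perturbations
  from the seed and participant index, and every evaluation function seeds
  fold assignment and forest training from its config. RNG state of the
  caller is saved and restored.
* Windows shorter than the nominal length, empty datasets after rejection,
  unknown tastes, non-numeric CSV cells and mismatched label sets all fail
  fast with labelled errors.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  synth = list(n_participants = 2, sessions = 1, seed = 5),
  eval  = list(rf_n_trees = 60, seed = 9)
)
res <- run_pipeline(cfg, "demo_out")
print(res$report)
summary(res$report)
```

The demo configuration (2 participants, 1 session, 12 trials) runs in a few
seconds; the default study grid (8 participants × 4 sessions) takes a few
minutes, dominated by the 255-subset grouping experiment when requested.
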