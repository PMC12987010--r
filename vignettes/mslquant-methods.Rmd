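---
title: "Quantifying motion sickness from multimodal physiological signals"
author: "mslquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion sickness from multimodal physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslquant)
```

## The problem

Motion sickness level (MSL) during simulated or visually induced vehicle
motion is usually measured subjectively — a simulator sickness questionnaire
(SSQ) before and after exposure, and a fast motion sickness (FMS) report on a
1–5 scale every 30 s during it. The scientific question this package
operationalises is how far MSL is also visible in objective multi-rate
physiological and behavioural streams: photoplethysmography (PPG, 128 Hz),
electrodermal activity (EDA, 128 Hz, recorded as skin resistance in kΩ),
8-channel EEG (500 Hz; F3, F4, C3, C4, P3, P4, O1, O2), skin temperature
(1 Hz), head pose (30 Hz), a head-mounted IMU (4 Hz), and binocular eye
tracking (30 Hz).

The package implements the full analysis chain as tested, reusable code:

1. **Timeline reconstruction** — recordings arrive as overlapping fragments
   with per-second chunk jitter; they are merged, edge-trimmed, and mapped
   onto a rate-exact expected sample grid.
2. **Per-sensor preprocessing** — fixed filter chains (notch, zero-phase
   band-pass, conductance conversion, common average reference, a pluggable
   EEG artifact hook, a 3-point temperature smoother).
3. **Windowed feature extraction** — an 828-descriptor registry of
   signal-wise features (SwF: a uniform 6 time + 2 frequency template per
   source signal) and window-derived features (WdF: heart-rate variability
   and Poincaré indices, EEG power ratios and functional-network
   connectivity, blink/gaze/vergence and head-kinematic summaries) over 38
   aligned 30-s windows per session.
4. **Questionnaire scoring** — SSQ/ΔSSQ, MSSQ with its quartic percentile
   polynomial and tertile grouping, Film IEQ subscales.
5. **Statistics** — repeated-measures correlation (rmcorr) with
   smallest-effect-size-of-interest (SESOI) tiers and Benjamini–Hochberg
   families.
6. **Contribution analysis** — an additive boosting model with pairwise
   interactions, global importances, domain ablation with the relative
   degradation rate Δm(%) = (m_full − m_abl)/m_full × 100, single-domain and
   lightweight-combination evaluation, and participant-wise cross-validation.

Because the original cohort recordings are not publicly deposited, a
synthetic-data module generates cohorts with the statistical structure the
analysis assumes — including ground truth, so every downstream stage is
testable end to end.

## The synthetic cohort model

### Latent trajectory and observation model

Each session carries a latent 1-Hz MSL trajectory: a logistic ramp whose
asymptote scales with a per-participant susceptibility scalar and a
session-type gain (composite stimulation 1.2, classical 1.0, visual-only
0.85), plus susceptibility-scaled AR(1) noise clamped at zero. The ramp
midpoint falls in the second half of the 1200-s session, reflecting symptom
accumulation with exposure. FMS observations are a clipped affine transform
of the latent value, quantized to the 1–5 scale with Gaussian report noise,
every 30 s. Zero susceptibility produces the identically zero trajectory.

### Signals and planted associations

Each stream is a baseline oscillatory/noise process whose amplitude (or
noise fraction) is modulated linearly by the latent trajectory through
signed loadings: a multiplier `max(1 + beta * z(t), 0.05)`. The default
loadings encode the reported effect directions: EDA phasic amplitude
decreases with MSL (−0.3), head pitch-rotation and surge-position energy
increase (+0.3), gaze-direction PSD entropy increases (+0.3), EEG sample
entropy decreases (−0.3). EDA is a tonic drift plus Poisson skin-conductance
responses (rise 0.5 s, decay 1.5 s — textbook SCR kinetics; the short decay
also keeps adjacent analysis windows nearly independent, which is what makes
the null calibration below meaningful); PPG is a harmonic pulse wave with a
slowly wandering heart rate plus the 30/60-Hz interference the preprocessing
chains are designed to remove; EEG is pink noise plus an occipitally
dominant alpha rhythm plus 60-Hz line harmonics; head pose and IMU are
narrowband oscillations with short-memory amplitude envelopes; eye tracking
is a narrowband gaze wander with blinks (some reported as null frames) and a
vergence target at 1–2 m.

What the generator does **not** emulate: real spectra and amplitude
distributions of human physiology (none are published for the study
population — amplitudes are free choices), motion-platform dynamics, film
content, ocular EEG artifacts, and body-joint streams. A passing test
therefore shows the *pipeline arithmetic* is right and recovers what was
planted, not that real cohort numbers are reproduced.

### Fragmentation and chunk jitter

Recording restarts split a session into fragments re-recorded from 10 s
before the stop (e.g. 0–500 s and 490–1200 s). The acquisition side
delivers samples in ~16-Hz chunks; scheduling latency moves boundary chunks
into the neighbouring one-second save block, so per-second stored counts
deviate by up to ±1 chunk while recorded timestamps carry only
OS-scheduling-scale noise (0.3 ms). We model the count artifact at the save-
block level and keep timestamps near-truth because only under that reading
can nearest-grid mapping plus interpolation reconstruct band-limited content
to sub-percent error — a ±1-chunk error in the *sampling clock* itself would
be unrecoverable at any rate. An optional chunk-dropout probability creates
genuine gaps that exercise the interpolation path.

## Numerical choices

* **Timeline.** Seams are placed at the overlap midpoint (the source
  procedure trims "at least 5 s on each side" without fixing the seam;
  the midpoint is symmetric and reproducible, and with the 10-s restart
  overlap it trims exactly 5 s per side). Nearest-index ties resolve to the
  earlier sample. Empty grid indices are filled with shape-preserving
  piecewise cubic Hermite interpolation (monotone data in, monotone
  interpolant out); boundary gaps take the nearest observed value rather
  than a Hermite extrapolation, avoiding edge overshoot — edges are trimmed
  away anyway. Grids are anchored at t = 0 of the merged stream.
* **Filters.** Notch and band-pass are realized as zero-phase spectral
  gains on the mirrored (even-extended) signal: complete stopband
  suppression, untouched passband, no group delay, and a whole chain
  collapses into a single FFT pass. Band-pass transition bands are 25% of
  each edge frequency (raised cosine), so attenuation one octave outside the
  band is complete. The engineering contract (≥ 20 dB in the notch, ≤ 1 dB
  passband ripple) is what the tests pin down; the attenuation depths of the
  original spectrum-fitting implementation are not published.
* **Welch spectra.** Hann taper, 50% overlap, density scaling. PPG/EDA: FFT
  8192 with 20-s (2560-sample) segments, to resolve the narrow 0.1–0.15-Hz
  LF band; EEG: FFT = segment = 2048 (≈ 0.24 Hz/bin); all other sensors:
  FFT = segment = rate × 20 s. The DC bin is always excluded and negative
  values clipped. Band edges are lower-inclusive/upper-exclusive except the
  last band of a partition, so the standard EEG bands partition the whole
  band exactly.
* **Entropies.** Sample entropy uses m = 2, r = 0.2 × segment SD, Chebyshev
  distance, in compiled code; a zero-variance segment is defined to have
  entropy 0 (the "no irregularity" limit). EEG sample entropy is computed
  after decimation to 125 Hz, EDA/PPG to ~16 Hz, purely for tractability of
  the quadratic-cost template matching. PSD and heatmap entropies are base-2
  (bits); any other base is a monotone rescaling.
* **Windows.** `floor(effective / 30)` aligned windows; fragment seams split
  a window into segments processed separately and averaged, as the
  segment-length-20-s Welch parameters anticipate. The FMS value of a window
  is the exact integral of the piecewise-constant report trajectory; before
  the first report, its value extends backward.
* **Kurtosis/skewness.** Excess (Fisher) kurtosis and the standardized third
  moment; both are undefined (missing) on zero-variance segments. Variance
  uses the n−1 denominator.
* **Head orientation.** Intrinsic yaw–pitch–roll angles are converted to
  quaternions; the window-average rotation is the chordal mean (sign-aligned
  component-wise mean, renormalized) — adequate for small intra-window
  rotations, and the averaging method is otherwise unconstrained. Relative
  rotations applied to the forward vector give the direction signals.
* **PPG window features.** Beats from an adaptive-threshold local-maxima
  detector with a 0.3-s refractory period; SD1/SD2 from the approximation
  formulas SD1 = RMSSD/√2 and SD2² = 2·SDNN² − SDSD²/2 (the fallback route,
  used here unconditionally for determinism); CSI = L/T and
  CVI = log₁₀(L·T) with T = 4·SD1, L = 4·SD2. LF/HF and breath rate come
  from the Welch spectrum of the 4-Hz-resampled, detrended inter-beat
  series; the breath rate is the dominant respiratory peak (0.1–0.5 Hz),
  reported within [4, 60] breaths/min. Fewer than 5 beats flags the whole
  window missing.
* **MSSQ percentile.** The printed polynomial subtracts its B term while the
  printed B constant is itself negative; the default evaluates everything
  exactly as printed, and `convention = "golding"` switches to the
  conventional all-positive-coefficient form. Results are clamped to
  [0, 100] (as printed, the polynomial exceeds 100 within the attainable
  score range). Which convention the original analysis used cannot be
  determined from the text, so both are exposed and the choice documented.
* **rmcorr.** Within-participant centering (the common-slope ANCOVA), df =
  N − k − 1, two-sided p, pairwise deletion, participants with fewer than
  two complete observations dropped. The exploratory feature–MSL screen is
  deliberately unadjusted for multiplicity; SESOI tiers (|r| > 0.20 / 0.25 /
  0.30, strict, jointly with p < 0.05) provide the effect-size gate, and
  Benjamini–Hochberg families serve the confirmatory questionnaire analyses.
* **Additive boosting model.** No interpretable-boosting implementation
  exists in this R environment, so the model is authored here: cyclic
  bin-wise gradient boosting of piecewise-constant shape functions (≤ 32
  quantile bins per feature, learning rate 0.2, early stopping on a seeded
  20% holdout used *only* for stopping), then pairwise interaction terms on
  a coarse 8 × 8 grid for the top candidate pairs (`interactions = 0.9` is
  read as that fraction of the feature count). Fit metrics (R², PLCC, SRCC)
  are computed in-sample on all rows, matching a full-dataset explanatory
  fit — whether the original printed metrics are in-sample or
  validation-split is not stated, and the in-sample reading is implemented.
  Importance is the mean absolute term contribution; interaction importance
  stays with the interaction term. Missing features are median-imputed
  within the training rows. All ablation/single-domain/combination refits
  reuse identical rows, hyperparameters and seed.

## Problem sizes used in the automated checks

The structural checks run at the study's printed geometry (1140-s effective
sessions, 128-Hz and 500-Hz grids, the 828-descriptor registry). The
planted-signal recovery study uses 30 participants × 3 sessions × 1200 s
with the EDA and head-pose streams and the headline feature per planted
family, over 20 generator seeds; the null calibration uses 12 participants
over 20 seeds with one feature per independently generated channel (14
channels across EDA, SKT, head pose and head IMU), so the trials behind the
binomial confidence interval are independent — several template features of
one signal share its windows and would not be; the contribution-model
recovery uses 12
participants over 10 seeds with one headline column per domain (three
features, three domains) so the ablation comparison is not confounded by
unequal domain sizes — the imbalance the single-domain evaluation exists to
address. These
sizes give the recovery rates stable denominators while keeping the whole
suite a desk-scale computation; the acceptance script reruns the same
quantities at slightly smaller seed counts.

## Known limitations

* The generator's amplitudes and spectra are schematic; no claim is made
  that they match the study population, and cohort-level statistics (ANOVA
  tables, real-data R²) are out of scope by design.
* The ICA-based EEG artifact stage is a pluggable hook with an identity
  default; the synthetic EEG contains no ocular artifacts to remove.
* The Film IEQ item-to-subscale map shipped here is a synthetic stand-in
  partition (9/7/4/4); only the partition property is relied on downstream.
* EDF export is not provided; sessions are written as per-sensor CSV plus
  JSON, which the timeline module reads back.
* rmcorr assumes a common within-participant slope; with autocorrelated
  window series its nominal p-values are only approximately calibrated —
  the generator keeps window-to-window memory short, and the null-
  calibration test quantifies the residual miscalibration.
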