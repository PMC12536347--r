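---
title: "Methods: simulation, feature bank and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, feature bank and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cogload)
```

This vignette documents the modelling choices behind `cogload`: what the
synthetic sessions emulate and deliberately do not, how each feature is
defined numerically, and how the cross-validated evaluation is kept free of
information leakage. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The simulation model

A session is a sequence of task blocks, each with an activity name, a
duration, and a latent cognitive-load level $L \in [0,1]$. The default
profile mirrors a single office-style protocol — a one-minute eyes-closed
baseline, ten minutes of relaxation, a game block, reading, summarising,
and a high-load task block — with latent loads $0, 0.1, 0.3, 0.5, 0.8, 1.0$
chosen so that the rounded questionnaire model
$\mathrm{response} = \mathrm{clip}_{1..5}(\mathrm{round}(1 + 4L + \varepsilon))$,
$\varepsilon \sim N(0, 0.3^2)$, populates all five response classes. The
label-noise SD of 0.3 keeps most labels faithful while letting borderline
blocks flip occasionally, which is what self-reports do.

Physiology couples to load through fixed per-unit slopes, every one of
which is multiplied by the profile's `effect_size` $e$, so $e = 0$ yields
physiology statistically independent of load:

| channel | coupling per unit $e \cdot L$ | baseline |
|---|---|---|
| heart rate | +8 bpm | 70 bpm (participant SD 5) |
| inter-beat jitter | −12 ms | 50 ms |
| EEG β amplitude (all channels), prefrontal θ | ×(1 + 0.35 eL) | δ/θ/α/β/γ = 20/10/15/8/4 µV RMS |
| SCR event rate | +1.5 per minute | 1 per minute |
| tonic skin conductance | +0.4 µS | 2 µS (participant gain lognormal) |
| skin temperature | −0.2 °C | 33 °C (participant SD 0.5) |

These slopes were chosen once, for physiological plausibility and so that
`effect_size = 1` sits in the middle of the discrimination range rather
than at ceiling; they are not tuning knobs. Within-session heart rate also
wanders slowly (SD 4 bpm, ~45 s timescale), which is what keeps a single
window's mean heart rate from being a noiseless load readout.

EEG is synthesised as FIR-bandpass-filtered white noise per canonical band,
scaled to the requested RMS amplitude — this gives exactly controllable
expected band powers without modelling neural dynamics. Phasic skin
conductance responses use the standard bi-exponential template (rise 1 s,
decay 4 s, peak-normalised). Tonic drifts are spline-interpolated sparse
Gaussian knots: sufficiently smooth that no drift energy leaks above the
0.05 Hz tonic/phasic boundary and masquerades as phasic activity. The PPG
is a peaked pulse (Gaussian systolic peak, small dicrotic bump) at beat
times integrated from the instantaneous rate with Gaussian inter-beat
jitter.

The two virtual devices run on clocks offset by 1.5 s by default, and both
sample one common band-limited (< 12 Hz) 3 s shake trajectory at session
start on their own clocks. The common trajectory matters: independent
high-variance bursts would give the motion-energy envelopes no sharp
cross-correlation peak and make sub-sample synchronisation impossible. A
single burst is an assumption — the emulated shake procedure is not
specified beyond its existence.

**What the generator does not emulate:** realistic EEG microstates or
1/f background, PPG waveform morphology beyond a peaked pulse, motion
artefacts, electrode pops, circadian drift, or any dependence of label
quality on the participant. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind it assumes*, not that real
recordings contain that structure.

## Preprocessing

Power-line interference (50 Hz, injected by the generator into the EEG) is
removed with a second-order IIR notch (quality factor 30) applied forward
and backward with mirrored edge padding of several notch time constants.
Channels whose rate cannot resolve 50 Hz — everything at 4–64 Hz — pass
through untouched, and no other artefact rejection is performed.

Synchronisation resamples both motion-energy envelopes to a common 32 Hz
grid, coarsely locates each burst as the maximum of 1 s-smoothed energy,
maximises the normalised cross-correlation over ±30 s, and refines the peak
lag by parabolic interpolation. A peak correlation below 0.5 is an error,
never a silent guess; the pipeline then falls back to the device-declared
offset with a warning.

Windows are non-overlapping 60 s slices cut inside task blocks
(trailing partial windows dropped, no window straddles a block boundary),
so each window carries exactly one activity and one questionnaire response
pair. Overlap-free windowing is the simplest reading of splitting a
recording into windows; nothing downstream assumes independence beyond it.

## The feature bank

The multilevel DWT uses db2 and haar at level 8 with symmetric extension
(verified coefficient-exact against the reference PyWavelets
implementation on fixed vectors). For each of the five source series (four
notch-filtered channels and their mean — the only combination consistent
with the 720-feature count) and each wavelet, the nine retained arrays
cA8, cD8…cD1 are summarised by eight statistics. Conventions that the
literature leaves open are pinned as: population (n) standard deviation;
skewness and kurtosis as standardised third/fourth central moments with no
excess adjustment; relative wavelet energy normalised over the nine
retained arrays; zero crossings as strict sign changes (exact zeros never
count). Degenerate (constant) coefficient arrays yield NaN moments, which
the evaluation treats as missing values.

Band powers are total periodogram power (rectangular window, mean removed)
over the bins strictly inside each band — the sum, not the per-bin mean, so
that a sine of amplitude $A$ contributes $A^2/2$ and white-noise band power
scales with band width. The six indices are a configurable registry with
pinned defaults: Engagement Index $\beta/(\alpha+\theta)$ and Brain Beat
$\theta/\alpha$ on the mean projection, Cognitive Load Index
$\theta_\text{prefrontal}/\alpha_\text{temporal}$, and hemispheric
asymmetries as right-minus-left log α power per region (their mean is ASA).
The exact formulas behind the index names vary across the literature; the
registry pins this package's versions so results are reproducible, and a
zero denominator produces a missing value while the window is retained.

Beat detection band-passes the PPG to 0.5–8 Hz, picks local maxima above
half the rolling 75th-percentile amplitude with a 330 ms refractory period,
and keeps NN intervals in 273–2000 ms. SDNN uses the sample (n−1)
convention. LF/HF powers integrate a Welch density (Hamming, 50% overlap)
of the NN series cubic-spline-resampled at 4 Hz; with fewer than 30 NN
intervals in a window the spectral fields are reported missing and flagged
`short_window` — a 60 s window is genuinely marginal for the 0.04 Hz LF
edge, and the flag makes that visible instead of hiding it.

The tonic EDA level is a centred 20 s rolling median — a zero-phase
estimator with the intended 0.05 Hz bandwidth ($1/20\,\mathrm{s}$) that is
robust to the phasic pulses themselves; a linear low-pass at the same
cutoff absorbs a large fraction of each SCR into the baseline and rings.
Phasic = signal − tonic, so the decomposition is exactly additive. SCR
peaks require 0.01 µS amplitude and 1 s separation (common practice;
nothing in the emulated setup pins them).

Feature counts are structural invariants: 5 × 2 × 9 × 8 = 720 wavelet
features, 16 spectral/index features, 18 wristband features, 754 in total.
The reduced sets (20 both-modalities, 20 headband, 18 wristband) are pinned
in `inst/extdata/feature_sets.json`; the twelve wavelet members draw on the
prefrontal electrodes, the haar wavelet, detail coefficients cD1/cD7/cD8
and the statistics Kurtosis, Mean and ZeroCrossing. The manifest is the
single source of truth — the table defining the sets names only "twelve
DWT-features", so the exact membership is a package decision, versioned so
it cannot drift silently.

## Labels, selection, evaluation

The 5-point workload response maps to the identity (5-class), to
low/neutral/high (3-class), and to low/high with the neutral response
**excluded** (binary) — "low and high" names only two poles, and dropping
the neutral windows is an explicit assumption. Eyes-closed baselines are
excluded from classification; the activity vocabulary for one-hot context
features is (Relaxation, Load, Summary, Reading, Game) in that fixed order.

Per-participant z-scoring is applied before fold splitting — deliberately
mirroring a per-participant normalisation that in a real deployment would
be computed on the participant's own calibration data; it uses no labels
and no cross-participant statistics, but it is flag-selectable
(`z_normalize = FALSE`) for a strictly fold-internal pipeline. Median
imputation and min-max scaling are always fitted on training rows only,
with test values clipped to [0, 1]; a leakage probe in the test suite
(a feature equal to the label on held-out rows only) verifies that this
buys no performance.

The hyperparameter grids reproduce the standard domains: tree criterion ×
splitter × depth 5–305 in steps of 5; logistic solver × penalty with
invalid combinations pruned; MLP activation × hidden size; KNN leaf size ×
neighbours × Minkowski p; linear SVM penalty × C. Backend notes: the
decision tree is fitted with rpart (depth is capped at 30 by rpart itself —
immaterial at these data sizes where depth never exceeds ~15 — and the
"random" splitter value is carried in reports while both values use
exhaustive best-split search); the logistic family is a glmnet penalised
likelihood, the solver label being bookkeeping; the MLP (single hidden
layer, softmax output, full-batch Adam, 300 epochs, seeded init), the exact
Minkowski KNN, and the one-vs-rest squared-hinge linear SVM (proximal
gradient for l1) are compact in-package implementations, each verified
against closed-form or reference behaviour in the tests. KNN's leaf size
parameterises a search data structure, not the predictions, so the default
grid samples it at {1, 10, 20, 30, 40, 50}.

Generalised models use leave-one-participant-out CV; per configuration the
held-out weighted F1 values are aggregated as min/mean/max, and the best
configuration per family maximises mean weighted F1 with ties broken by
smaller hyperparameter magnitudes, then lexicographic label (the selection
rule itself is a package decision). Personalised models use stratified
k-fold (default 5) within each participant, optionally with the one-hot
activity features; each participant's (min, mean, max) over folds is
averaged across participants. Degenerate folds (a class absent from
training) are scored anyway and flagged rather than dropped — with ten
participants they are unavoidable and silently discarding them would bias
the aggregates. `loo_cv_null()` provides the label-permutation null of the
mean weighted F1 for calibration checks.

## Problem sizes used by tests and the acceptance script

The packaged checks run on deliberately scaled-down studies, the package's
own choice of simulation size: single sessions at one-fifth scale
(~10 min) for structural and planted-truth checks, and 10-participant
studies at one-third scale (~16 min, ~15 windows per participant) for the
calibration suite — binary LOO-CV with a logistic configuration at effect
sizes {0, 0.5, 1, 2} averaged over 3 seeds, a 50-permutation null band at
effect 0, and the ≥ 0.80 skill check at effect 2. Module invariants quoted
at 20 seeds in their definitions are sampled at 3–20 seeds depending on
their per-seed cost. Full-scale sessions (46 min) and the full grids remain
available through the exported surface.

## Known limitations

* The synthetic EEG has flat-band (not 1/f) spectra and no transients, so
  wavelet statistics are better behaved than on real recordings.
* LF HRV power on 60 s windows is marginal by construction and flagged, not
  corrected.
* Device clock offset is modelled as constant; clock drift is out of scope.
* The index formula registry pins one defensible version of each workload
  index; published variants differ, and conclusions about any single index
  should not be ported across formula versions.
* Real-data validation (`validate_real_data()`) exercises the identical
  code path but its outputs are not part of any packaged check: the
  recordings must be downloaded separately, and fold- and selection-level
  details of published analyses are not reproducible from summary numbers
  alone.
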