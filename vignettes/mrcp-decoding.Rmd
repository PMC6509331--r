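---
title: "Decoding attempted hand movements from movement-related cortical potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attempted hand movements from movement-related cortical potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Persons with cervical spinal cord injury (SCI) largely lose voluntary hand
and arm function, but the cortical commands for attempted movements are
still issued. Movement-related cortical potentials (MRCPs) — slow
(sub-3 Hz) deflections of the EEG over sensorimotor cortex around movement
onset — carry information about *which* movement was attempted. A
brain-computer interface that classifies attempted hand open, palmar
grasp, lateral grasp, pronation and supination from low-frequency EEG
could drive a grasp neuroprosthesis with a natural control paradigm.

`mrcpdecode` implements the full analysis chain for this setting twice
over:

* an **offline pipeline**: cue-based 5-class trials, a four-step artifact
  removal procedure, shrinkage-LDA classification of lagged time-domain
  samples in a sliding window with repeated cross-validation, and
  group-level statistics (difference topoplots with a max-statistic
  permutation test, Cz peak analysis with Friedman tests, t-based
  confidence intervals, adjusted-Wald chance thresholds);
* an **online proof-of-concept**: a go-cue training paradigm, a 5-class
  classifier (two movement classes, rest, and auxiliary *pre*/*post*
  classes), and a causal, self-paced detection state machine evaluated by
  true-positive rate, false positives per minute and 2-class accuracy.

Because the human recordings cannot ship with a package, a first-class
synthetic EEG generator reproduces the paradigms' schedules and the
class-dependent MRCP morphology, so every stage has known ground truth.

## The synthetic generator

### What it emulates

A session is a continuous 61-channel (10-5 system) + 3-EOG recording at
256 Hz with an event stream. Three paradigms are generated:

* *offline*: 9 runs of 40 trials; each trial shows a fixation cross at
  `trial_start`, the class cue 2 s later, lasts 5 s, and is followed by a
  uniform 1–3 s break — 72 trials per class;
* *online training*: 5 movement runs of 30 trials (class cue at trial
  start, ready cue at 2 s, go cue after a uniform 0.5–1 s hold plus a
  2–4 s shrink period) and 4 rest runs of 70 s;
* *online test*: runs of 4 movement + 1 rest trial; a 5-s cue then a 60-s
  self-paced period in which attempts occur at randomized times (several
  seconds apart) and are "reported" about 2 s later, with ±0.3 s jitter
  so the true-positive-window offset search is non-trivial.

The MRCP template is a two-lobe waveform: a positive lobe (cue
processing) followed by a negative lobe (the movement-related
negativity). Gaussian lobes of width 0.2 s (positive) and 0.3 s
(negative) are fixed, documented constants; the two lobe coefficients are
solved from a 2×2 linear system so the waveform passes exactly through
the drawn peak amplitudes at the drawn latencies. The per-class peak
statistics default to the descriptive values measured on Cz in the SCI
study population (e.g. pronation: +8.01 µV at 0.44 s, −5.48 µV at
1.10 s). A morphology toggle adds a second negative lobe for short
(non-sustained) attempts, and the online paradigms scale the positive
lobe to 0.3× because their go cue elicits a weaker cue-processing
potential.

### Hierarchical parameter draws

The tabulated standard deviations describe variability *across
participants* of participant-level class averages. Treating them as
per-trial jitter would be a misreading with visible consequences: with a
0.59 s trial-level latency spread, averaging 72 jittered trials flattens
and shifts the class-average peak, so the generator would not reproduce
the very statistics it was parameterized with. The generator therefore
draws each session's class templates once from the across-participant
distributions and adds smaller within-session trial jitter (amplitude
coefficient of variation 0.15, latency sd 0.03 s by default). A session's
class average then converges to its own template as 1/√n, and the mean
over simulated participants converges to the tabulated means.

### Noise and artifacts

Background noise is 1/f ("pink") Gaussian noise per channel (default
4 µV RMS, flat below 0.1 Hz), plus 50 Hz line interference (2 µV), blinks
(4/min, 80 µV biphasic deflections projected fully onto the EOG channels
and with decaying gain onto frontal EEG rows), single-channel transient
bursts (1/min, 150 µV) and optionally channels ruined by strong
wide-band noise. The MRCP projects through a radial spatial gain centred
on Cz (unit gain there, ≈0 at temporal sites).

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: spatially correlated background EEG,
volume-conducted EMG, electrode drift and popping, non-stationary
alpha/beta rhythms, and any realistic head geometry. The generator's
purpose is verifiable ground truth, not biophysical fidelity.

## Preprocessing

The four-step cleaning procedure:

1. **Bad channels** — AFz is removed by default (blink-sensitive); other
   channels are flagged when their robust amplitude (log MAD) deviates
   from the channel population by more than 4 robust z-units. This is a
   documented automated stand-in for visual inspection; the threshold is
   exposed.
2. **Stationary artifacts** — extended Infomax ICA (`ica::icaimax`) on
   0.3–70 Hz data, after PCA reduction to the components explaining 99%
   of variance, fitted only on samples within 10.4 MADs of the channel
   median (≈7 standard deviations for normal data; the MAD is
   unnormalized). Components are flagged when their time course
   correlates with an EOG channel at |r| ≥ 0.7 or when their 40–70 Hz
   band power exceeds twice their 1–15 Hz power (muscle-like spectrum) —
   again an automated stand-in for manual selection, with both thresholds
   exposed. The ICA weights are cached.
3. **Transient artifacts** — trials are marked by a ±100 µV amplitude
   bound, by an abnormal joint probability (the per-trial mean negative
   log-probability of its samples under per-channel histogram densities
   pooled over trials; 100 fixed-width bins), and by abnormal kurtosis;
   the latter two flag trials more than 5 standard deviations above the
   across-trial mean of their statistic. The union of flags rejects.
4. **Application** — the cached ICA weights are applied to the 0.3–3 Hz
   narrow-band signal, flagged components are removed, and the cleaned
   channels are back-projected; marked trials are excluded.

Filtering uses Butterworth designs from the `signal` package: a
band-pass of design order 4 (the classic `butter(4, band)` convention,
eight poles) applied forward–backward for the zero-phase offline variant
(zero group delay, squared magnitude), or single-pass for the causal
online variant. Causal filters are initialized at their steady-state
response to the first sample (implemented by constant padding), because
the online path classifies from the first seconds of the stream; without
this the onset transient of a 0.3 Hz high-pass lasts several seconds.

## Decoding

Features are raw microvolt samples of all good EEG channels at lags
spaced 200 ms apart in a window of 0–1.4 s (channel-major ordering);
offline windows are symmetric about the evaluation time, online windows
are causal. After common-average re-referencing, a multiclass shrinkage
LDA is fitted: the pooled within-class covariance is shrunk towards
ν·I (ν = mean diagonal) with an analytic Ledoit–Wolf/Schäfer–Strimmer
intensity — the ratio of the summed sampling variances of the covariance
entries to the summed squared deviations from the target, clipped to
[0, 1]. Discriminant scores pass through a softmax to give class
probabilities; exact ties resolve to the lowest class index. The window
slides in 1/16-s steps; accuracy at each position is estimated by
repeated stratified trial-based 10×10 cross-validation (folds partition
trials, never samples; fold assignments are reshuffled per repeat from a
single seed stream and reused across window positions so curves are
comparable along time). The 3-class grasp-subset analysis is the same
code under a different class list.

## Group statistics

Difference topoplots average the absolute pairwise differences of the
trial-averaged class potentials over all class pairs, then over
non-overlapping 250-ms segments spanning 0–3 s after the cue (12
segments). Bad channels are interpolated beforehand with a thin-plate
(biharmonic) spline — the r²·log r radial basis plus an affine term, so
constants and linear gradients are reproduced exactly.

Significance uses a one-tailed max-statistic permutation test: class
labels are shuffled within each participant at the trial level, the grid
recomputed, and both the observed and the permuted grids centred on the
permutation mean; the null distribution is the maximum of the centred
permuted grids over all channels and segments, and cells whose centred
observed value exceeds its 1−α quantile are flagged. The centring is the
package's design choice where the procedure was ambiguous: building null
maxima from `observed − permuted` directly would embed any true effect in
the threshold itself and leave the test without power, while the centred
form preserves both the family-wise error control (verified by Monte
Carlo in the test suite, 200 null runs) and power against injected
effects. The default permutation count is 1000 (not prescribed; exposed).

Cz peak features are the maximum in 0.2–0.9 s and the minimum in
0.7–2.5 s after the cue — fixed, documented search windows, since the
peaks are defined only descriptively; degenerate geometry (wrong
ordering, boundary peaks) is flagged rather than silently accepted.
Friedman tests across classes use `stats::friedman.test`; confidence
intervals over participants use the t-distribution; the
better-than-chance accuracy threshold is the upper bound of the adjusted
Wald (add z²/2) interval around 1/k at level α/m, with the trial count
and Bonferroni divisor m exposed because published thresholds are not
recomputable without the study's post-rejection trial counts.

## The online detector

Training epochs are aligned to the go cue. `t_train` is the grid time
(1–2 s after the go cue, 1/16-s steps) with the highest 10-fold 3-class
cross-validated accuracy (earliest on ties). The 5-class training set
takes movement-class features at `t_train`, *pre* and *post* features
from both movement classes at `t_train` ∓ 500 ms, and rest features cut
from the 70-s rest runs so the rest class matches the movement trial
count.

The detector scans the causal probability trace: with reference point
t₀ = t − 650 ms, a detection fires at t when (1) the pre-class
probability exceeds 0.7 for ≥150 ms within [t₀−650, t₀−350] ms, (2) a
movement-class probability exceeds 0.9 within [t₀−50, t₀+50] ms, and
(3) the post-class probability exceeds 0.7 for ≥150 ms within
[t₀+350, t₀+650] ms. The detected class is the movement class with the
higher maximum probability in the movement window; a 2-s refractory
period follows. Dwell time is counted in whole samples
(⌈0.15·rate⌉) and cumulatively by default — "above threshold for at
least 150 ms within the window" admits a consecutive reading, which is
available as a configuration switch. The classifier is evaluated at
every sample of the 256 Hz stream by default; a coarser cadence is a
configuration option used by the fast test configurations.

The expected detection delay is `t_train + 500 ms + 75 ms` (distance to
the post-window centre plus half the dwell), a conservative average
maximum. The true-positive window is 2 s long and centred `offset`
seconds after each reported attempt; the offset is chosen by maximizing
the TP/FP detection ratio over a 0–5 s grid in 0.1-s steps (step not
prescribed; 0.1 s resolves the report jitter). Zero-FP offsets dominate
any finite ratio and are ranked among themselves by TP count; remaining
ties resolve to the smallest offset. FP/min is computed from rest trials
only (their 60-s post-cue periods); detections in movement trials outside
the TP windows enter only the offset search. The online path applies the
same channel policy and common-average reference as the offline
classifier, with causal filtering and no ICA.

## Numerical and scale choices

* Sample indexing is 0-based in event onsets; epoch ranges are half-open.
* All simulations are driven by R's Mersenne-Twister generator seeded
  from the configuration; identical seeds give byte-identical sessions.
  Pipelines derive participant seeds from the master seed by fixed
  offsets.
* The test suite and the acceptance script run the full-size *schedules*
  (72 trials/class offline, 150 movement trials online) where trial
  counts are the point, but use the reduced 19+3-channel montage, a
  subset of window positions, 2 cross-validation repeats and modest
  permutation counts for the heavier end-to-end checks; component-level
  statistical tests run at 64 Hz on template-built epochs. These sizes
  are the package's own choice of desk-scale defaults; every operation
  accepts the full-scale settings.
* Monte-Carlo acceptance checks use tolerance bands derived from the
  sampling variability of the quantity under test (e.g. 3.2 standard
  errors for peak recovery over six simulated participants) rather than
  fixed cosmetic tolerances.

## Known limitations

* Synthetic noise is spatially white, so ICA separates artifacts more
  cleanly than on real EEG; thresholds tuned here should be re-examined
  on recorded data.
* The heuristic channel/component screening replaces expert judgement; it
  is reproducible but not validated against the study's manual choices.
* Published significance thresholds that depend on unpublished
  post-rejection trial counts are recomputed from this package's own
  inputs and logged, not matched.
* The online replay is a sample-by-sample simulation of the causal path,
  not a real-time system; timing jitter, buffering and amplifier effects
  are out of scope.
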