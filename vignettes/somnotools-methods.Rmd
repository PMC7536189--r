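---
title: "somnotools: models and methods"
author: "somnotools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnotools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnotools)
```

somnotools analyses chronic mouse EEG/EMG sleep recordings together
with Morris water maze (MWM) performance. This vignette explains the
models behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices that shape the results.

## Sleep staging

Recordings (2 EEG derivations + 1 EMG, 400 Hz, microvolts) are divided
into non-overlapping 4-s epochs, each scored WAKE, NREM or REM.
`score_epochs()` uses the classic electrographic signatures:

* **WAKE** — high muscle tone: epoch EMG RMS above
  `emg_wake_threshold` (default 2) times the recording-wide median of
  per-epoch EMG RMS. The multiplicative form makes the rule invariant
  to EMG gain. Epochs with neither muscle tone nor a dominant spectral
  peak (mixed-frequency EEG) also score WAKE, which covers quiet
  wakefulness and keeps the rule meaningful in recordings that contain
  little or no sleep, where the median self-normalisation saturates.
* **REM** — theta-dominant EEG with atonia: theta/delta power ratio
  above `theta_delta_ratio_rem` (default 1), at least
  `rem_theta_fraction` (default 0.3) of total epoch power inside the
  theta band (6–9 Hz, peak expected at 7–8 Hz), and EMG RMS below
  `rem_atonia_fraction` (default 0.6) of the wake cut-off.
* **NREM** — delta dominance: at least `nrem_delta_fraction`
  (default 0.6) of total power inside 0.5–4 Hz.

Band powers come from a Hann-windowed periodogram per epoch (0.25-Hz
resolution at 4-s epochs). Epochs whose EEG exceeds
`artefact_amp_bound` (default 1000 µV) are flagged as artefact and
excluded from all spectral and event analyses. Epochs partially
overlapping the end of the recording are discarded.

`macro_metrics()` reduces a hypnogram to total sleep time
(TST = NREM + REM), per-state minutes, the NREM:REM ratio (undefined
when no REM is present — flagged, never coerced to a number), episode
statistics and the arousal index. The literature rarely defines
"arousal" operationally; here an arousal is a maximal run of 1–4 WAKE
epochs (≤ 16 s) flanked by sleep on both sides, and the arousal index
is arousals per minute of TST. A sleep episode is a maximal stretch of
sleep permitting embedded arousals with at least 3 sleep epochs. Both
bounds are arguments, so their influence can be examined directly; the
defaults are stated here once and used everywhere.

## NREM event detection

All filtering uses a zero-phase (forward–backward) fourth-order
Butterworth band-pass (`bandpass_phase_neutral()`), applied **per
contiguous artefact-free NREM run** — never across the seams of
concatenated runs, which avoids filter transients at state
transitions. Runs shorter than three filter lengths are skipped.

**Slow oscillations** (`detect_slow_oscillations()`): the 0.4–4.5 Hz
trace is segmented at its negative-to-positive zero crossings
(crossings located at sample-pair sign changes, boundary on the later
sample; at 400 Hz the 2.5-ms quantisation is negligible against the
0.4-s minimum duration, so no sub-sample interpolation is done).
Segments lasting 0.4–2.0 s are candidates; the top 35% by most
negative peak are kept, and of those the top 45% by
negative-to-positive peak-to-peak amplitude. Both cuts keep
`floor(q × n)` segments after a descending sort with ties broken by
earlier start, so with n strictly distinct candidates exactly
`floor(floor(0.35 n) × 0.45)` (≈ 15.75%) survive. Amplitudes are
measured on the filtered trace. The percentile criteria are scale-free:
rescaling the signal leaves the selected set unchanged.

**Spindles** (`detect_spindles()`): the 10–16 Hz trace's Hilbert
envelope is smoothed with a 200-ms moving average and thresholded at
mean + 1.5 SD of the smoothed envelope over artefact-free NREM of the
whole span (per recording-day, matching per-24-h reporting). A spindle
is a maximal supra-threshold run of 0.4–2.0 s; its onset is the first
supra-threshold sample. Runs touching an NREM-run boundary are
discarded rather than truncated. Because the threshold is
mean + k·SD, the detected intervals are exactly invariant to amplitude
rescaling.

A consequence worth stating: the 10–16 Hz filter (≈ 6 Hz bandwidth)
plus the 200-ms smoother give the envelope a rise time of roughly
300–350 ms. The threshold-crossing onset therefore carries a
systematic offset of a few tens of milliseconds that depends on where
the threshold sits on the rising edge, and a per-event jitter of
similar size from the background envelope. On generator output at
default settings the median absolute onset deviation is ≈ 35–40 ms;
individual events can deviate by 100 ms or more, and isolated
high-amplitude bursts in otherwise quiet recordings are detected
*early* (the threshold then sits low on the smeared edge). Onset
accuracy claims for this detector class are meaningful as central
tendencies, not per-event guarantees.

`summarize_events()` reports counts and densities per NREM minute;
events with zero NREM time are rejected as inconsistent input.

## Phase-amplitude coupling

`compute_modulation_index()` quantifies the dependence of spindle-band
amplitude on slow-wave phase. Per contiguous artefact-free NREM run,
the slow band (0.4–4.5 Hz) and fast band (10–20 Hz) are extracted with
the same zero-phase filters; the Hilbert transform gives the slow
phase φ and fast amplitude A. Runs shorter than 10 s are excluded and
1 s is trimmed from each run end (Hilbert edge effects). Samples are
pooled across runs — pooling, rather than per-run averaging, follows
the canonical formulation of the entropy-based index — and assigned to
12 equidistant bins over (−π, π] (left-open, right-closed; centres at
−π + (k − ½)π/6). Each bin is summarised by the **median** of A, a
deliberate robustness choice over the more common mean, and the
profile is normalised to a distribution P. The modulation index is

MI = KL(P ‖ uniform) / log 12 = (log 12 − H(P)) / log 12,

with natural logarithms (the normalisation makes the base irrelevant).
MI is 0 for a flat profile, 1 when all mass falls in one bin, and
invariant to positive rescaling of the signal (up to floating-point
bin hops at phase-bin edges, below 1e-3 in practice). Empty bins are
reported as an error, never imputed. `surrogate_shift_s` circularly
shifts the pooled amplitude series — the standard surrogate control:
genuine coupling collapses (below 20% of the unshifted MI at moderate
coupling) while both marginal distributions are preserved.
`mi_by_day()` computes one index per 24-h block and flags blocks with
insufficient NREM as missing rather than zero. `mi_from_profile()`
scores a constructed or published bin profile directly.

## Water maze

Trajectories are time-tagged x–y positions in a pool-centred frame
(cm); the default geometry is a 200-cm pool with a 10-cm platform at
60 cm radial distance and a drop point near the opposite wall. Route
efficiency is 100 × (straight drop-to-platform distance) / (swim path
length up to first platform contact), capped at 100 — the cap absorbs
the small overshoot that arises because a real path ends at the
platform edge while the direct distance is measured to its centre.
`trial_metrics()` adds time to target (censored at 120 s), path
length, mean speed and dwell-weighted quadrant occupancy (pool-frame
quadrants rotated so the platform quadrant comes first; accumulation
stops at platform contact).

`classify_strategy()` assigns one of seven categories in a first-match
cascade — thigmotaxis, random search, scanning, chaining, directed
search, focal search, direct swimming — scored 0/0/0/0/1/2/3. The
numeric thresholds are *not* universal constants; published
classifiers differ between laboratories, so every zone size and
cut-off lives in `strategy_config()` and the classifier is validated
against the synthetic archetypes (the fidelity target is the category
semantics and the 0–3 ranking). Three exclusion clauses are essential
to make a first-match cascade work: chaining and directed search
require that fewer than half the samples lie within 20 cm of the
platform (otherwise focal search, which orbits the platform at its
radial distance, matches the chaining annulus or the goal corridor
first); scanning requires minimum pool coverage and at most 5% of
samples beyond 0.8 pool radii (otherwise concentrated focal paths or
cross-pool corridors pass as central scanning); directed search
requires route efficiency below 80% (otherwise direct swims match the
wider corridor first). `strategy_ranking()` averages scores per
training day, the standard summary of strategy progression.

## The synthetic-data generator

The generator exists to give every stage a ground truth. It is a
phenomenological signal model, not a biophysical one.

* **Hypnogram**: a first-order Markov chain at 4-s resolution. The
  default matrix enters REM only from NREM and has a stationary law of
  roughly 43% wake, 50% NREM, 7% REM with mean bouts of 30–45 s —
  typical for the mouse. Keeping wake below half the recording also
  keeps the scorer's median-EMG normalisation on the sleep mode.
* **EEG background**: a 1/f floor (spectrum flattened below 0.75 Hz)
  plus band-limited noise components with state-dependent SDs —
  delta-weighted in NREM (25 µV), a 6.5–8.5 Hz theta component in REM
  (12 µV), broadband in wake — so NREM spectra peak in 0.5–4 Hz and
  REM spectra in 6–9 Hz, the signatures the scorer relies on.
* **Slow oscillations**: 10 per NREM minute by default, down-state
  magnitude ~N(120, 15) µV, up-state 0.7× the down-state. The template
  spans a support drawn from 0.6–2.1 s: a small negative lead-in (8%),
  the up state (37%), the down state (47%) and a small positive tail
  (8%). The lead-in and tail pin negative-to-positive zero crossings
  to 8% and 92% of the support, so zero-crossing segmentation recovers
  the inserted cycle as one candidate of valid duration. The delta
  background is damped by 70% under each event (an SO locally
  dominates the slow band), and the template is smoothed with a 25-ms
  Gaussian because slope discontinuities would otherwise leak
  phase-locked harmonics into the spindle band and fabricate coupling.
* **Spindles**: 5 per NREM minute by default, 12-Hz bursts of 0.5–1.5 s
  under a flat-topped envelope with 10-ms ramps, envelope peak at 5×
  the measured 10–16 Hz background SD. The steep envelope keeps the
  detector's threshold crossing close to the true onset.
* **Placement**: deterministic spacing (rate-exact counts, the default)
  assigns one event per equal slot of concatenated NREM with uniform
  jitter inside the slot. The jitter matters: perfectly periodic
  placement of both families locks every spindle to a fixed phase of
  the SO spacing cycle and fabricates phase-amplitude coupling where
  none is configured. A Poisson mode is available. Events that cannot
  be placed without touching a run boundary or a same-type neighbour
  are dropped from signal and ground truth alike. Rates so high that
  events would tile more than half of NREM are rejected.
* **Coupling**: with depth m > 0 the spindle-band component (background
  and bursts) is multiplied by 1 + m·cos φ within NREM, where φ is the
  Hilbert phase of the composed slow signal. The default is m = 0:
  coupling is an experimental knob, switched on explicitly by analyses
  that study it.
* **EMG**: white noise at state-dependent RMS (wake 30, NREM 10,
  REM 4 µV). No twitch artefacts.
* **MWM archetypes**: constant-speed (20 cm/s) 25-Hz paths whose
  geometry matches each strategy's signature (wall annulus, confined
  centre, platform-distance annulus, widening goal corridor, platform
  orbit, straight line), terminating at platform contact or 120 s.

What the generator does **not** emulate: biophysical waveform shapes,
frequency drift within events, slow/fast spindle classes, transition
dynamics beyond first-order, EMG artefacts, light/dark-phase structure,
inter-animal spectral variability beyond the exposed knobs, or video
tracking noise. Passing recovery tests on this generator therefore
demonstrates that the detectors implement their stated criteria
correctly and recover known events under realistic spectra and SNR —
it does not certify performance on real recordings, where artefact
structure and waveform variability are richer.

With the default rates, the percentile-based SO criteria return about
15.75% of all duration-valid slow-wave segments; the defaults place
the implanted events (~10/min) just inside that budget against a
background candidate rate of ~57/min, so recall and precision are both
high (≈ 0.95 and ≈ 0.92 on 30-min runs). A percentile detector
over-calls by construction when true events are rarer than its
percentile budget — a property of the criteria, not of this
implementation.

## Statistics

The battery mirrors standard practice for this design: Student paired
and unpaired two-sided t-tests (equal variances — no Welch correction,
which would otherwise be a silent change of test), one-way
repeated-measures ANOVA with Mauchly's sphericity test and
Greenhouse–Geisser correction applied when sphericity is rejected at
0.05 (the fit is delegated to `car::Anova` on a multivariate linear
model; an independent sums-of-squares and epsilon oracle in the test
suite verifies F, ε and p to 1e-10), Pearson correlation with
two-sided t-transform p-values, Shapiro–Wilk normality checks, and
Bonferroni adjustment `min(1, m·p)`. Degenerate inputs (zero-variance
samples, missing cells) raise errors rather than numbers, with one
exception: identical paired samples return t = 0, p = 1, which is the
informative answer. In `rm_anova()` a zero between-condition sum of
squares likewise returns F = 0, p = 1 rather than 0/0.

`build_report()` applies the comparison structure to per-animal,
per-condition metric tables: unpaired group tests within each
condition (raw and Bonferroni-adjusted over conditions), paired
baseline-versus-learning tests within each group (the learning value
of an animal is the mean over its learning days), and Pearson panels
over learning-condition values (spindle count vs arousal index,
arousal index vs NREM duration and NREM:REM ratio, a proliferation
covariate vs NREM:REM ratio, NREM duration and spindle count vs route
efficiency), pooled and per group. Missing cells use listwise deletion
with a logged notice.

## The pipeline and problem sizes

`run_pipeline()` chains simulate → score → detect → couple → MWM →
report for a two-group cohort and writes CSVs; identical
configurations yield byte-identical files. Default sizes — 3 animals
per group, 20-min recording blocks, 2 MWM days of 6 trials — keep a
full run under a minute while exercising every stage; they are scaled
study stand-ins, chosen so the pipeline remains a practical regression
harness, and are not presented as a power-adequate experiment. The
test suite uses 20–60-min recordings for detector and scorer checks
and 1-h all-NREM recordings for coupling sweeps.

## Numerical choices and edge cases

* Zero-phase filtering uses `signal::filtfilt` without end padding;
  tests and detectors avoid the first and last filter lengths of a
  run where transients live (events touching run boundaries are
  discarded anyway).
* The Hilbert transform is computed by FFT one-sided spectrum
  doubling; run lengths are multiples of the epoch sample count, which
  keeps FFT sizes highly composite.
* Percentile ties are broken by earlier start time; `floor` is used at
  both cuts so the retained count is exact and reproducible.
* The moving-average smoother is centred with shrinking windows at the
  edges (no group delay).
* Seeds: every stochastic routine takes or derives an explicit seed
  and restores the caller's RNG state; sub-streams are derived with a
  fixed linear map so stages are decoupled.
* EDF export digitises to 16-bit integers with per-channel symmetric
  physical ranges; round trips are exact to the digitisation quantum.
  Recordings are padded to whole 1-s records with a warning.

## Known limitations

* The scorer is rule-based and tuned to the generator's clean state
  signatures; real recordings with transitional epochs or artefact
  families beyond amplitude saturation will need threshold review.
* Spindle onset timing inherits the envelope rise-time limits
  discussed above.
* The strategy thresholds are documented stand-ins; applying the
  classifier to real tracking data should start from a calibration
  against hand-scored trials.
* No light/dark-phase split, sleep-onset latency, probe-trial
  analysis, or slow/fast spindle subclassification.
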