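---
title: "Quantifying the nociceptive withdrawal reflex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the nociceptive withdrawal reflex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwreflex)
```

## The measurement problem

Noxious electrical stimulation of the index finger evokes a coordinated
short-latency withdrawal of the arm, mediated by Aδ-fiber input to the motor
pools of several upper-limb muscles. Two families of observables quantify
this reflex:

* **Surface EMG** from eight muscles — APB, BRD, BBL, TRI, AD, PD, and the
  right/left erector spinae as postural monitors — from which per-muscle
  *onset latencies* (ms after stimulus) and *mean rectified amplitudes* are
  extracted per stimulation trial.
* **Endpoint forces and moments** at the wrist from a six
  degree-of-freedom transducer sampled at 200 Hz, from which the planar
  (X–Y) *withdrawal force vector* — magnitude and direction — is computed
  per trial. By convention +X points to the subject's right, −Y toward the
  subject, so the stereotyped posterior-lateral withdrawal lands in the
  fourth quadrant. Fz and Mz are excluded throughout: with the limb
  supported they mostly carry gravitational load that varies with arm
  configuration.

The package implements this chain end to end — epoching, the reflex EMG
processing chain, force-vector extraction, condition averaging, and the
statistical layer for two experimental designs: reflexes probed in five
static arm positions (plus a repeated neutral position as a habituation
check), and reflexes probed before and after 200 trials of voluntary
extension (EXT) or flexion (FLEX) practice.

## The EMG chain

Each stimulus train (10 pulses, 200 µs, 300 Hz; eight trains per condition
at 5–15 s jittered intervals) defines an epoch spanning 100 ms before to at
least 350 ms after the train onset. Every channel is epoched on its own
clock against the shared event time; no resampling or interpolation is ever
performed, so threshold crossings are reported at sample resolution. All
windows in the package are closed–open `[start, end)` in ms.

Per muscle and trial:

1. **DC removal** subtracts the full-epoch mean (the epoch is the unit the
   chain operates on, and offset removal precedes any windowing).
2. **Rectification** takes the absolute value. Downstream operations refuse
   un-rectified input, which pins the processing order at the API level.
3. **Baseline statistics**: mean and sample SD (n−1) of the rectified
   signal in the 100 ms immediately preceding the stimulus.
4. **Onset detection**: the latency is the first sample in `(0, 200]` ms at
   which the rectified EMG exceeds `mean + k·SD` of the baseline (`k = 3`)
   and stays above that threshold throughout `[t, t + min_above_ms]`.
   `min_above_ms = 0` reproduces the literal first-crossing rule;
   the default of 2 ms debounces isolated spikes at any sampling rate
   (every sample in the closed 2 ms span must exceed the threshold).
5. **Quantification**: the response amplitude is the mean rectified EMG
   over `[onset, offset)`. The offset criterion of the source recordings is
   not numerically specified anywhere, so `offset_ms` is a configuration
   parameter; its default of 200 ms matches the reflex analysis window,
   the only post-stimulus bound stated for the analysis.
6. **Averaging**: the eight trials of a condition are averaged per muscle;
   trials without a detected onset are excluded and counted
   (`n_trials_used`), and muscles with zero detections (typically the
   erector spinae) are reported absent rather than zero.

Degenerate inputs are handled explicitly: an all-zero baseline (mean 0,
SD 0) triggers a warning and detection proceeds against threshold 0; an
onset landing exactly at the end of the search window leaves an empty
response window and yields an absent amplitude; events too close to the
recording edges are skipped with a logged warning rather than failing the
whole recording, since no exclusion rule is documented for them.

An optional `blank_ms` parameter zeroes the first milliseconds of the
search window to skip stimulation artifacts; it is off by default.

## Force-vector analysis

Per trial and axis, the trace is baseline-corrected by subtracting its mean
over the same 100 ms pre-stimulus window (this removes the configuration-
dependent gravitational bias), and the *local peak* is the in-window
extremum in the expected direction — maximum for Fx (+, lateral), minimum
for Fy (−, posterior) — within `(0, 200]` ms for reflex trials or
`(0, 350]` ms for practice trials. The two axes peak independently by
default, reflecting the paired peak-Fx/peak-Fy reading of the measure; a
`simultaneous_peak` flag instead reads both axes at the single time of
maximal planar norm. Moments Mx/My use the largest absolute deflection with
sign retained. The resultant is `magnitude = sqrt(Fx² + Fy²)` and
`direction = atan2(Fy, Fx)` in degrees, counterclockwise from +X, in
`(−180, 180]`; a zero vector has an undefined (absent) direction.

Across trials, magnitudes and per-axis peaks average arithmetically while
directions average circularly (vector mean of unit vectors), which is
immune to wrap-around at ±180°. Whether the study averaged per-trial
vectors or took the vector of averaged peaks is not documented; per-trial
computation followed by averaging was chosen because the per-trial vectors
are also the unit entering the trial-level variability displays. Directions
entering *linear* statistics (t-tests, ANOVA) are first unwrapped onto the
360° branch centred on their circular mean — the statistical layer then
treats them as plain numbers, a documented caveat of using linear
statistics on angles.

## Statistical layer

Significance is judged at α = 0.05 throughout.

* **Joint-position comparisons** use ANOVA with arm position as the fixed
  factor and subject as a random factor. With one summary value per
  subject × condition cell this mixed model reduces exactly to the
  repeated-measures ANOVA with subject blocks, fitted as
  `aov(value ~ condition + Error(subject))`. When the omnibus rejects,
  all pairwise position contrasts are tested with paired t-tests under
  Bonferroni adjustment (`min(1, p·m)` over the family of pairs). The
  repeated neutral condition is *excluded* from the omnibus; it is compared
  against the initial neutral with independent t-tests as the habituation
  check (independent, not paired, to mirror the documented analysis even
  though a paired test would be natural — fidelity over preference).
* **Practice comparisons** use two-sided paired t-tests pre vs post within
  each practice type, on every per-muscle measure and force measure.
  Between EXT and FLEX (tested on different days), measures are compared as
  percent change `(i2 − i1)/i1 · 100` with independent t-tests — except
  onset latencies, which are compared as the absolute change in ms, and
  summarized per subject × muscle in a signed (+/−) change grid.
* Degenerate data (zero residual variance, zero difference variance) raise
  informative errors rather than numeric exceptions.

A structural identity links the two test families: on two conditions the
repeated-measures F equals the square of the paired t statistic. The test
suite asserts this on random matched data, which cross-checks the ANOVA
reduction against an independent closed form.

## The synthetic-data generator

The generator exists so that every downstream stage is testable against
known ground truth. It emulates, per subject × condition bundle:

* **Baseline EMG**: stationary Gaussian noise with the power spectrum of a
  zero-phase 4th-order Butterworth band-pass (20–450 Hz, clipped below
  Nyquist), matching the pass band of typical surface-EMG conditioning
  hardware, plus a constant electrode DC offset (so DC removal is
  exercised). The realization is synthesized spectrally, which is the same
  law as time-domain zero-phase filtering at a fraction of the cost.
* **Reflex bursts** in the six upper-limb muscles (never in the erector
  spinae): an asymmetric-Gaussian envelope with a fast attack (5% to peak
  in 0.25 ms) and slow decay (5%-to-5% duration 40 ms), carrying a
  deterministic component plus band-limited stochastic modulation,
  `A·env(t)·(1 + m·noise)` with `m = 0.05` and `A = 5` baseline SDs by
  default. The abrupt coherent attack mimics the synchronized afferent
  volley of the short-latency reflex. A purely stochastic
  amplitude-modulated burst was rejected at the design stage: a band-limited
  Gaussian carrier crosses zero every couple of milliseconds, so its
  rectified trace dips below any threshold near every zero crossing and a
  *sustained* 3-SD crossing cannot track the envelope onset to within
  ±2 ms — the accuracy the generator is required to support by design.
  With the defaults, the detector recovers the true onset within ±2 ms in
  ≈95% of trials (mean absolute error ≈ 0.6 ms, detection rate ≈ 100%).
  The ground-truth onset is the 5% point of the envelope.
* **Latencies**: per-muscle means in the 50–100 ms range (PD 78 ms and
  BRD 86 ms anchored to reported group values; the others plausible within
  the range), a per-subject shift (SD 8 ms) shared across conditions, and
  trial-to-trial jitter (SD 5 ms). Within-subject trial variability is not
  reported anywhere, so the 5 ms default is a stand-in chosen below the
  11–18 ms *between-subject* SDs that fold in subject variance.
* **Forces**: Fx/Fy follow a smooth Gaussian-profile ramp-to-peak-and-decay
  reaching the planted magnitude (default 5 N) at 120 ms in the planted
  direction (default −55°, posterior-lateral), with per-subject direction
  (SD 5°) and magnitude (log-SD 0.15) effects, per-trial scatter, white
  measurement noise, and a constant per-condition gravitational bias that
  the baseline correction must remove. Mx/My are lever-arm-scaled copies of
  the planar forces; Fz/Mz carry only slow drift, as they are excluded from
  analysis. An optional ~4 ms stimulation artifact after t0 exercises the
  blanking option.
* **Design**: eight trains per condition at inter-train intervals uniform
  on [5, 15] s; six bundles per subject for the joint-position task (five
  positions plus the repeated neutral), four for the conditioning task
  (pre/post × EXT/FLEX). `effect_deltas` plants per-condition shifts of
  latency, amplitude, direction, or magnitude — the null case (all zero) is
  the basis of the type-I calibration studies. The 200 practice trials
  themselves are not simulated: practice stimulation is sub-reflex by
  design, and only the pre/post reflex assessments enter the statistics;
  the 350 ms practice force window is exercised through the
  `force_window_ms` configuration.

Everything is deterministic given `(seed, spec)`; changing only the seed
changes the samples but not the layout.

What the generator does *not* emulate — and hence what green tests do not
show about real recordings: EMG cross-talk between neighbouring muscles,
motor-unit structure and non-Gaussian interference patterns, habituation or
wind-up across trials, movement artifacts, non-stationary baselines, and
any systematic coupling between EMG amplitude and force output.

## Validation studies and problem sizes

The shipped validation suite (and `scripts/acceptance.R`, which recomputes
the same quantities from scratch) runs:

* **Detector–oracle equivalence**: 1000 random epochs across rates
  500–2000 Hz, amplitudes 3.5–8 SD, debounce settings 0–5 ms, including
  noise-only channels; the vectorized detector must equal an exhaustive
  per-sample scan in 100% of cases.
* **Latency recovery**: 80 trials at the default spec; detection rate
  ≥ 95% and mean absolute onset error ≤ 2 ms.
* **Closed forms**: peak (3, −4) N → magnitude 5 N at −53.130°; rotation
  and scale equivariance over 100 random transforms; percent change of the
  78 → 84 ms latency pair = +7.692%.
* **Type-I calibration**: 1000 replicate null experiments (4 subjects,
  2 trials, 500 Hz — sizes chosen to keep the full
  generate-detect-summarize-test chain per replicate cheap without changing
  the null), omnibus and paired rejection rates within 3 Monte-Carlo SEs
  of 0.05.
* **Planted-effect recovery**: 20 experiments (10 subjects, 4 trials,
  1000 Hz, 2 ms jitter) with a +6 ms PD-only latency shift after extension
  practice; the PD contrast must reject in ≥ 90% of replicates while the
  unshifted muscles stay at the null rate. 1000 Hz is used here because at
  500 Hz the 2 ms debounce spans only two samples and rare early noise
  crossings (~4% of noise-only trials) contaminate trial means.
* **Reproduction pathway**: the deposited recordings of the original
  practice study are not redistributable with the package, so the group
  pre/post reproduction path runs on a synthetic stand-in with the reported
  PD change planted (78 → 84 ms) and must recover both group means within
  sampling error.

## Numerical and design notes

* Onset times are reported at sample resolution; no sub-sample
  interpolation. Sample counts for windows use the closed–open convention;
  the debounce span is closed (`floor(min_above·rate/1000) + 1` samples).
* The EMG sampling rate of the original recordings is not stated (only an
  amplifier gain is documented), so the recording format requires an
  explicit per-channel rate and the synthetic default is 2000 Hz.
* Baseline SD uses the n−1 denominator (conventional sample SD; the choice
  is not documented in the source analyses).
* `aov` with an `Error(subject)` stratum is used for the subject-random
  ANOVA; its two-condition case is cross-checked against `t²` identically.
* The internal layout of externally deposited data folders is not
  documented; `read_recording()` therefore accepts an editable YAML adapter
  (template in `inst/extdata/deposited_adapter.yaml`) mapping external
  files and column names onto the package's bundle schema. The template's
  values are placeholders to be confirmed against the actual files.
* Known limitations: linear statistics on angular direction (after branch
  unwrapping) mirror the original analysis but are approximate for widely
  dispersed directions; the erector spinae channels can produce occasional
  noise-driven "detections" under the bare threshold rule at low sampling
  rates — real analyses should treat muscles with near-zero detection
  counts as non-responding, as `summarize_condition()` reports them.
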