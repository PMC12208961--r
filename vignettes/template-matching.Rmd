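---
title: "Automated template matching for ECG-free heartbeat detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated template matching for ECG-free heartbeat detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomatch)
```

## The detection problem

Cardiomechanical signals — SCG (chest acceleration), GCG (chest angular
rate), FCG (chest-wall force) — record the vibrations the beating heart
imparts to the chest wall. Each heartbeat appears as a short wave packet
whose energy sits mostly in the 7–30 Hz band, riding on respiration,
posture drift and broadband noise. Marker-based beat detection (locating a
named fiducial peak per beat) fails when morphology varies, which it does
across sensors, subjects, postures and — most severely — cardiac
pathology. Template matching sidesteps markers: it only assumes that,
within one recording, beats resemble *each other*. One representative beat
is selected as a template, and normalized cross-correlation (NCC) of that
template against the whole signal turns every occurrence of the beat into
a sharp, amplitude-invariant correlation peak.

`cardiomatch` implements the fully automated version of this method: the
template is selected algorithmically, so the chain from raw waveform to
inter-beat intervals (IBIs) involves no operator judgement.

## Pipeline and parameters

### Conditioning

* SCG/GCG (and pre-differentiated FCG): 4th-order Butterworth band-pass,
  7–30 Hz, applied zero-lag.
* Raw FCG: the respiratory component is estimated with a Savitzky–Golay
  smoother (polynomial order 3, frame ≈ 1.5 s, the nearest odd sample
  count) and subtracted; the remainder is band-passed as above and
  differentiated by forward difference (`out[n] = (x[n+1] - x[n])·fs`),
  yielding the dHF-FCG signal used for detection.
* ECG (reference only): 0.5–40 Hz band-pass plus a powerline notch bank —
  second-order IIR notches of quality factor 35 at the 50 Hz fundamental
  (configurable to 60 Hz) and every harmonic below Nyquist, each applied
  zero-lag.

"Zero-lag" is realized as forward–backward filtering of the stated-order
filter, so the effective magnitude response is the squared single-pass
response and the phase response is identically zero — beat timing is never
biased by filter group delay. Finite records are extended by odd
(point-symmetric) reflection at both ends before filtering; the pad length
is ten periods of the lowest cutoff frequency, which lets the slow 7 Hz
edge transient decay below 1e-9 before any retained sample. Records
sampled below 500 Hz are first oversampled to 1 kHz by linear
interpolation, which bounds the quantization of beat times by the coarse
grids of low-rate devices.

### Automatic template selection

The record is scanned in consecutive, non-overlapping 10 s windows
starting at t = 0 (a trailing partial window is not searched). Per window:

1. **Envelope.** `E = lowpass_3Hz(x^4)`, 2nd-order zero-lag Butterworth,
   clipped at zero and normalized to its own maximum within the window.
   The 4th power sharpens beat packets against background; normalizing
   makes the subsequent thresholds scale-free.
2. **Beat candidates.** Envelope local maxima with topographic prominence
   ≥ 0.25 (on the 0–1 scale) are taken as heartbeats.
3. **Reliability gate.** A window qualifies if (a) it holds at least 5
   beats — the count implied by a minimal plausible heart rate of 30 bpm
   over 10 s — and (b) the mean absolute deviation of its IBIs is below
   335 ms. The bound comes from the most rhythm-variable arrhythmia:
   atrial fibrillation SDNN is 117.9 ± 72.2 ms, so under normality 99% of
   SDNN values fall below 117.9 + 3·72.2 = 334.5 ms; IBI variability above
   that is more plausibly spurious envelope peaks than rhythm
   (`selection_gate_derivation()` recomputes both numbers). MAD rather
   than SD because a 10 s window holds few IBIs and SD is outlier-fragile.
4. **Scoring.** In the first reliable window, each beat is segmented from
   200 ms before to 500 ms after its envelope peak (beats whose support
   overruns the window are dropped). Every candidate is correlated with
   every other; candidate *i*'s score is `mean(r_i) / sd(r_i)` over its
   n−1 correlations, and the top scorer becomes the template. The ratio
   rewards beats that are similar to all others *consistently* — the beat
   expected to match the most heartbeats in the record.

Numerical guards: the SD in the score is floored at 1e-12 (all-identical
candidates would otherwise divide by zero), and exact score ties resolve
to the earliest beat, making selection deterministic. Envelope values are
clipped at zero before normalization since low-pass ripple can undershoot;
an all-flat window raises a typed degenerate-segment error and is treated
as unreliable by the scanner. Millisecond-to-sample conversions use
`round(ms · fs / 1000)`.

### Matching and beat reconstruction

NCC is the sliding zero-normalized Pearson correlation: at lag *k*, both
the template and the signal window starting at sample *k* are
mean-subtracted and divided by their root sums of squared deviations.
Values lie in [−1, 1] and are invariant to any affine rescaling of either
input — the property that makes the detector immune to sensor gain and
respiratory amplitude modulation. Zero-variance windows are defined to
correlate 0 (not NaN). The implementation uses an FFT cross-correlation
with cumulative-sum window statistics; a literal per-lag `cor()` loop
(`ncc_brute_force()`) ships with the package and the test suite holds the
two equal to 1e-10.

Beats are NCC local maxima with prominence ≥ 0.5 and minimum separation
0.5 s (within the exclusion distance the higher peak survives; equal
heights resolve to the earlier). A peak at lag *k* is reported at time
`(k + anchor)/fs`, where `anchor` is the envelope-peak position inside the
template — so reported beat times refer to the same physiological instant
regardless of which beat became the template. No padding is applied at the
record ends: a beat whose full template support does not fit inside the
record is undetectable by construction.

### Evaluation layer

Reference beats (ECG R peaks from the built-in Pan–Tompkins detector, or
ground truth) partition time into cardiac cycles at the midpoints between
consecutive reference beats, the first and last cycles extending to the
record bounds. Each detection belongs to the cycle containing it; the
detection nearest the reference beat in its cycle is a true positive, all
others in that cycle are false positives, and empty cycles are false
negatives. This operationalizes "multiple peaks in one cycle are FPs,
cycles with no peak are FNs" deterministically and one-to-one; the counts
satisfy `TP + FN = cycles` and `TP + FP = detections` by construction,
and the implementation is tested against a literal re-implementation of
the rule. An optional absolute tolerance (used with synthetic ground
truth, ±100 ms in the tests) additionally demotes nearest-detections that
are too far from the reference beat.

IBI agreement excludes every interval touched by an error: a reference IBI
enters the analysis only if both bounding beats are TP-matched and no FP
falls between their matched detections. Surviving pairs feed (a) OLS
regression of detected on reference IBIs with t-based 95% CIs and an R²
CI via Fisher z-transform of the correlation, and (b) Bland–Altman
analysis: Shapiro–Wilk at α = 0.05 decides between the parametric branch
(bias = mean difference, limits of agreement = bias ± 1.96 SD, standard
CI formulas) and the percentile branch (bias = median, LoA = 2.5th/97.5th
linear-interpolation percentiles, CIs from a seeded 2000-resample
bootstrap). For n > 5000 the normality test uses a deterministic stride
subsample of 5000, keeping the branch decision reproducible.

## The synthetic generator

`generate_record()` emulates the structure of real paired
cardiomechanical/ECG recordings so every pipeline stage is testable
without data downloads. Its defaults are the package's reference study
conditions; each was chosen once, for the reasons below, and the tests are
run under them.

* **Heartbeat kernel**: a systolic Gabor complex (15 Hz carrier, 120 ms
  support) plus a diastolic complex (12 Hz, 80 ms) at +320 ms with 40%
  amplitude — two-complex morphology with energy inside the 7–30 Hz
  analysis band, the shape these sensors record. The systolic peak is the
  ground-truth beat time.
* **Rhythm**: IBIs are `60000/HR + AR(1) + RSA`. The AR(1) term
  (coefficient 0.4, stationary SD defaulting to 5% of the mean IBI —
  heart-rate variability scales with cycle length) models beat-to-beat
  variability; the respiratory sinus arrhythmia term (default 30 ms at
  0.25 Hz) modulates IBIs at the breathing rate. IBIs are floored at
  300 ms, and parameter sets that would clamp more than 5% of beats are
  rejected as implausible.
* **Respiratory amplitude modulation**: ±15% at the breathing rate.
  Within the envelope detector's dynamic range ((1−d)/(1+d) must exceed
  0.25^(1/4) ≈ 0.707, i.e. d ≲ 0.17, for every beat's 4th-power envelope
  peak to clear the fixed 0.25 prominence), this reproduces the regime of
  quiet breathing at rest — the recording condition of the cohorts this
  method targets — in which template-search windows are ordinarily
  reliable. Deeper modulation reproduces the unreliable-window regime and
  remains available for stress tests.
* **Noise**: an equal-power mix of white and 1/f (pink) noise, scaled so
  the realized 7–30 Hz in-band power ratio equals `snr_db` (the tests
  verify ±1 dB). Default 15 dB; the parameter-recovery runs use 20 and
  10 dB.
* **ECG channel**: Ricker-wavelet QRS complexes with P and T bumps at
  `truth_beats − 40 ms` (a fixed electromechanical delay; only IBI
  *differences* matter downstream, so the constant cancels in every
  agreement statistic).
* **Pathological preset**: per-beat morphology jitter (±40% atom
  amplitude, ±20 ms atom latency), IBI SD 60 ms, SNR 10 dB — unstable
  morphologies for stress-testing, with no claim of clinical realism.
* **Artifacts**: `inject_spurious_bursts()` adds 100–300 ms Hann-windowed
  noise bursts, band-passed to 7–30 Hz (artifacts disturb detection only
  through their in-band content) and scaled relative to the channel RMS,
  optionally confined to or excluded from declared intervals.

Generation is bit-reproducible given the seed. What the generator does
*not* emulate: motion artifacts with structured (gait-like) periodicity,
posture-dependent morphology changes, sensor saturation, and genuinely
non-stationary noise. Passing tests on these records therefore demonstrate
algorithmic correctness and calibration of the statistical layer, not
field performance on ambulatory data.

## Problem sizes used in the checks

The packaged checks run on synthetic records of 30–120 s at 256–1000 Hz:
long enough that every stage (window scanning, reliability gating,
matching, agreement statistics on ~100–200 beats) is exercised with
realistic beat counts, while a full suite completes in well under a
minute. The statistical-layer calibrations use 500 seeded replicates of
n = 5000 for regression-CI coverage and n = 10⁴ differences for the
Bland–Altman parametric limits.

## Known limitations

* **Long cardiac cycles admit spurious peaks.** The NCC peak rules are
  fixed (prominence 0.5, separation 0.5 s). When the cycle length exceeds
  ~1 s (heart rate below ~60 bpm), a stretch of the cycle lies ≥ 0.5 s
  from both true-beat NCC peaks, and any local NCC maximum there survives
  distance pruning. Two effects make such maxima common: (1) in windows
  that contain mostly noise, NCC is variance-normalized, so its
  fluctuations do not shrink as the signal-to-noise ratio improves; and
  (2) the deep anti-correlation valleys flanking every true-beat peak
  (template half-overlap) lower the prominence reference level of
  mid-cycle peaks, so peaks of height only ~0.2 acquire prominence ≥ 0.5.
  At 50 bpm on otherwise clean synthetic records the package measures
  sensitivity 100% but PPV near 60–75%; at 70 bpm and above both are at
  or near 100%. Downstream IBI statistics are protected by the FP/FN
  exclusion rule, which is why the limits of agreement stay within a few
  ms even at 50 bpm. Users analyzing bradycardic recordings should widen
  `ncc_min_distance_s` accordingly.
* **Single channel, single template.** No multi-channel fusion and no
  template adaptation over time; a recording whose morphology drifts away
  from the selected template will lose sensitivity.
* **Transfer-function filtering.** Filters are applied in
  transfer-function form (as in the standard zero-phase implementations
  of the field's tooling). At a 7 Hz edge on a 1 kHz grid this amplifies
  rounding to ~1e-7 relative, which is why the linearity tests assert
  1e-6 rather than machine precision; second-order-section filtering
  would tighten this but is not provided by the filter-design dependency.
* **The evaluation layer trusts its reference.** R-peak errors of the
  Pan–Tompkins stage propagate into TP/FP/FN counts; with synthetic
  records the ground-truth channel avoids this entirely.

## A small worked run

```{r example}
p <- synth_params(duration_s = 60, mean_hr_bpm = 70, snr_db = 20, seed = 1)
s <- generate_record(p)
det <- detect_heartbeats(s$record, channel = "scg")
det
evaluate_agreement(det$beats$beat_times_s, s$truth_beats)
```
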