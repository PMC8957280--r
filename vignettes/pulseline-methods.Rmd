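---
title: "Extracting heart rate and HRV from short windows: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting heart rate and HRV from short windows: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseline)
```

`pulseline` estimates heart rate (BPM) and time-domain heart rate
variability (HRV) from a single cardiac channel, window by window, and
decides automatically which windows to trust. This vignette explains the
model behind each stage, the parameters that matter, what the bundled
synthetic-signal generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. Signal model and preprocessing

The input is a uniformly sampled amplitude series with a known sampling
rate: ECG (each beat a P–QRS–T complex, with the R peak the fiducial beat
marker) or PPG (each beat a systolic blood-volume pulse, often with a
secondary dicrotic bump). Three stages prepare it for detection:

* **Cubic-spline upsampling** (`resample_rate`, default 1000 Hz). Peak
  *timing* is the quantity HRV lives on: at 20 Hz a raw sample grid
  quantizes interbeat intervals to 50 ms, swamping an RMSSD of 20–50 ms.
  The spline interpolant passes exactly through every original sample, so
  upsampling adds temporal resolution without moving the data.
* **High-pass Butterworth filter** (`highpass_hz`, default 0.5 Hz).
  Removes DC and slow drift (respiration, perfusion, electrode drift) so
  the per-window 0–100 scaling is not consumed by baseline excursions.
  The order (2) and pass direction are design choices: the filter is
  applied forward and backward (`filtfilt`), giving zero phase — peak
  times must not shift — at the price of a squared magnitude response,
  which is documented behavior (the stopband is deeper, the −3 dB point
  slightly higher than a single pass). Cardiac content at ≥ 0.7 Hz (42
  BPM) passes with gain ≥ 0.99.
* **Savitzky–Golay smoothing** (`smooth_ms` 100 ms, `smooth_order` 3).
  Local cubic least squares: polynomials up to order 3 — and with them the
  rounded summit of a beat — pass through unchanged, while single-sample
  spikes are attenuated to the kernel's center tap. The window is rounded
  to the nearest odd sample count and must hold at least `order + 2`
  samples. Edges are mirror-padded; the sliding-window analysis consumes
  edge distortion anyway.

The stage order (upsample → filter → smooth) keeps the filter design
independent of the input rate. Non-finite input samples are a hard error
by design: silently imputing artifacts here would undermine the outlier
screens downstream, whose job is exactly to judge artifact-bearing
windows.

## 2. Windowed detection

Analysis slides a fixed window (width 10 s, movement 10 s by default)
across the recording; a trailing partial window is dropped. Ten-second
windows are an established compromise for ultra-short HRV: long enough for
~8–20 intervals, short enough to track state changes and to localize
artifacts. Overlapping windows (`window_overlap_s`, e.g. 9 s for 1 s
movement) buy temporal resolution at the price of serially dependent
estimates — a caveat for downstream statistics, not for extraction.

Within a window, samples are scaled affinely so min → 0 and max → 100,
making the amplitude threshold (`min_amplitude`, default 50) gain-free.
"Height" is the scaled value itself (distance from the window minimum).
Local maxima below the threshold are discarded; among maxima closer than
`min_distance_ms` (250 ms, a 240 BPM refractory bound) the taller wins.
Each surviving peak carries its topographic prominence and its width at
half prominence — the features that separate wave types.

**ECG clustering.** Amplitude-only detection confuses tall T (or P) waves
with R waves in atypical ECG. With `ecg_prt_clustering = TRUE` the
threshold drops to a near-zero floor (5) so P/R/T candidates are all
captured, and k-means (k = 3) partitions them on (width, height,
prominence). Choices the method leaves open, fixed here: features are
z-scored per window (their units are incommensurable); 10 restarts under a
fixed internal seed (reruns must be bit-identical); the R cluster is the
one maximizing *prominence z − width z* (R waves are narrow and
prominent), ties broken toward the narrower cluster. With fewer than 6
candidates or degenerate features, clustering is impossible; the window
falls back to plain thresholded detection and is flagged
(`clustering_fallback`) — flagged, not rejected, because a fallback is
information, not evidence of artifact.

**Edge re-imputation.** A window can open mid-beat, so the first/last
peak's prominence base may sit on a partial waveform (e.g. a P wave),
underestimating its amplitude and tripping the MAD screen spuriously. The
edge peak's prominence is recomputed against its interior neighbour's
baseline (height − prominence); interior peaks are untouched.

## 3. Metrics

With k peak times t₁ < … < t_k (seconds) and intervals IBIᵢ (ms):

* BPM = (k − 1) · 60 / (t_k − t₁).
* RMSSD = √( Σ (IBIᵢ − IBIᵢ₊₁)² / (N − 1) ), N the interval count — the
  divisor is the number of successive differences, the standard
  convention, pinned by a worked unit test (intervals 800, 750, 820, 790
  → 52.60 ms).
* SDNN and SDSD use the sample (n − 1) denominator.
* PNN20/PNN50 use strict inequality (|Δ| > 20, > 50 ms), so PNN50 ≤ PNN20
  always.
* HF power: the interval tachogram is spline-interpolated to a uniform
  4 Hz grid and the 0.15–0.4 Hz band's share of a mean-detrended
  periodogram, times the tachogram variance, is reported in ms². The
  estimator itself is a documented package choice; the normative part of
  the contract is `NaN` on insufficient data (< 4 intervals or a beat span
  < 6.7 s, one period of 0.15 Hz).

All intervals are carried in milliseconds — the physiological screening
bounds (5–262 ms) are only meaningful there.

**A windowing caveat.** The mean of per-window RMSSDs is not an unbiased
estimate of the recording-level RMSSD: the square root is concave, so a
window with only m successive differences underestimates by roughly
3·RMSSD/(8m) when intervals are serially uncorrelated — about −4 ms at
RMSSD 80 and 60 BPM. This is a property of every ultra-short-window
method, visible in the package's own simulations (peak-timing error is
only ~0.3 ms SD, so detection is not the culprit); pooling all detected
intervals across the recording avoids it when a single summary per
recording is wanted.

## 4. Outlier screening

The screen distinguishes two series. The *uncleaned* series demands only
computability: at least `min_peaks` (3, the minimum for RMSSD). The
*cleaned* series additionally demands:

* **Biological plausibility.** BPM and RMSSD strictly inside the preset's
  ranges (bounds exclusive). `moderate`: 30–190 BPM and 5–262 ms (the
  2nd/98th percentiles of resting RMSSD across adulthood); `liberal`:
  20–200, 0–300; `conservative`: 40–180, 10–200.
* **Statistical regularity.** Every peak height, prominence, and interbeat
  interval within the preset's MAD threshold (7 / 5 / 4 units for liberal
  / moderate / conservative) of the window median, where a MAD unit is
  |x − median| / median(|x − median|) without the normal-consistency
  factor. MAD is computed per window only — a median across windows would
  let one bad epoch contaminate its neighbours' screens. When the MAD
  degenerates to 0 (over half the values identical), a value differing
  from the median by more than a relative epsilon is flagged: a spike
  among identical values is precisely the artifact this rule targets.
* **Coverage.** Peaks spanning at least half the window width, so a "10 s"
  estimate is never secretly a 3 s estimate.

These thresholds nest (conservative ⊂ moderate ⊂ liberal), so cleaned
retention is monotone in the preset, and cleaned ⊆ uncleaned by
construction — both are property-tested. One inconsistency in the
method's published description had to be resolved: the minimum-peaks
formula *(width/5) + 2, floored at 3* yields 4 for a 10 s window, while
the stated default is 3; the explicit value is honored (`min_peaks = 3`,
configurable).

On *clean* high-SNR data the MAD screens are deliberately strict and will
reject windows for minor deviations (our noiseless simulations retain
~50–70% of windows under `moderate`); that is the documented reason to
relax to `liberal` for laboratory-grade recordings, and the package keeps
the uncleaned series alongside for exactly this judgement.

## 5. The synthetic-data generator

The generator exists to make parameter recovery measurable: it emits the
waveform *and* the labelled beat times, with `true_bpm` / `true_rmssd_ms`
computed by the package's own metric formulas (one definition of truth).

* **Interval model.** IBIs are i.i.d. Gaussian, mean 60000/BPM ms, SD =
  target RMSSD/√2 (successive differences of i.i.d. values have twice the
  variance, so the expected RMSSD equals the target), clamped at ±3 SD and
  floored at 250 ms. This is the simplest process with an analytic RMSSD
  target. It is *not* a cardiac dynamics model: real interval series are
  serially correlated (respiratory sinus arrhythmia), which concentrates
  per-window RMSSD around the long-run value. The i.i.d. model is the
  *hardest* case for window-subset agreement — per-window true RMSSD has
  an SD of ~10 ms at RMSSD 50–90 — so recovery statistics here are
  conservative relative to smoother generators.
* **Waveforms.** PPG: unit systolic Gaussian at each beat (SD 6% of the
  local interval) plus a dicrotic bump (+30% of the interval, amplitude
  0.4, SD 12%). ECG: narrow R (amplitude 1, SD 10 ms), P before (−18%,
  0.2, 30 ms), T after (+30%, 0.3, 50 ms), so R ≥ 3× P, T and clustering
  has honest work to do. Amplitudes are constant across beats — real
  sensors show beat-to-beat amplitude modulation, which (having nonzero
  spread) actually *calms* the MAD height screen; passing tests on this
  generator therefore does not certify retention rates on real data.
* **Noise and rate degradation.** White Gaussian noise at a requested SNR,
  with signal power taken mean-removed (a DC offset must not count as
  signal). Downsampling is pure resampling onto the coarse grid — exact
  decimation at integer factors — with **no anti-alias filter**, a
  deliberate and load-bearing choice: the degradation experiments add
  noise at 1 kHz first, and a low-rate acquisition of that noisy process
  keeps the full noise power in-band (aliasing). An anti-aliased resample
  would silently remove ~98% of the noise at 20 Hz and make the lowest
  rates the *cleanest* condition, inverting the entire noise-degradation
  pattern the validation is meant to exhibit.
* **Determinism.** All randomness flows from the recording's single seed;
  identical specs give bit-identical recordings.

The simulated "anxiety" experiment draws each subject's resting RMSSD
from N(23, 7²) ms truncated to [5, 262] (BPM from N(74, 13²)), and a
threat-condition RMSSD reduced by a per-subject difference drawn from
N(d·7, 7²). A deterministic shift of d·7 would make the paired
difference SD zero and the true paired Cohen's d infinite; giving the
difference the population SD makes the true paired d equal d in
expectation, so the estimated effect can be compared against both the
design value and each repeat's realized truth.

## 6. Validation statistics

* **ICC(A,1)** — two-way, absolute-agreement, single-measure intraclass
  correlation from the McGraw–Wong mean squares; unlike Pearson r, a
  constant offset between truth and estimate is penalized. Tested against
  an independent `aov()`-based computation. Semantic bands: < 0.5 poor,
  0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent.
* **RMSE**, with missing estimates excluded pairwise and counted.
* **Cohen's d**, paired (mean difference / SD of differences) and from a
  paired t statistic (d = t/√n, n = df + 1 pairs; t₂₅ = 1.96 → 0.384).
* **Paired-t sample size** from noncentral-t power, by doubling bracket
  plus binary search; two-sided by default — which reproduces the design
  value n = 171 for d = 0.384, α = 0.001, power = 0.95, resolving the
  open question of sidedness.
* **Jerk magnitude** for triaxial accelerometry: per-axis Δa/Δt, then
  √(jx² + jy² + jz²), averaged over the recording — a rotation-invariant
  proxy for wrist-motion severity (property-tested with random
  rotations).

## 7. Numerical choices and degenerate inputs

* Constant windows cannot be scaled ("degenerate window") and are
  excluded from both series with a machine-readable reason.
* Peak plateaus resolve to their midpoint; prominence bases stop at the
  nearest strictly higher sample or the window edge; width crossings are
  linearly interpolated.
* Zero-phase filtering uses odd (point-reflection) padding sized to ~3
  filter time constants so edge samples see a warmed-up filter state;
  plain `filtfilt` zero-padding leaks step transients.
* Resampled grids never extrapolate: the output grid spans
  `floor((n−1)·target/rate) + 1` points inside the original time range.
* The k-means seed, restarts, and tie-breaks are fixed; `analyze()` on
  identical input is bit-identical, which the suite asserts.

## 8. Problem sizes in the shipped checks

The package's own test suite runs reduced designs chosen to finish
comfortably on one CPU: a 3 × 4 BPM × RMSSD grid with 2-minute recordings
for the recovery pattern (the qualitative contrasts — excellent recovery
in benign cells, collapse near 0 dB, cleaning rescuing intermediate noise
— are all asserted there), and a 40-subject, 3-repeat anxiety simulation
checked against the n = 40 Monte-Carlo confidence band of d = 0.384. The
acceptance script runs the full-size designs (273 five-minute recordings
per condition cell) and reports the headline numbers; with this
generator the cleaned-RMSSD RMSE in the cleanest cells lands at 3–4 ms
rather than the ~2 ms a smoother, serially correlated interval process
yields — the window-subset effects of Sections 3 and 4 are the entire
difference, and the uncleaned RMSE (~1.5–2 ms) shows the detector itself
is not the limit.

## 9. Known limitations

* No ectopic-beat correction or cross-window imputation: a rejected
  window is a gap, by design.
* Frequency-domain HRV beyond the single HF estimate, nonlinear indices,
  and QRS delineation are out of scope.
* The generator does not model respiratory sinus arrhythmia, beat-to-beat
  amplitude modulation, or motion artifacts; conclusions about retention
  rates and absolute agreement on real wearable data require the optional
  PhysioNet benchmarks, not the simulations.
* Multi-channel files and binary formats (EDF/WFDB) are not parsed
  natively; the benchmark script shells out to a converter.
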