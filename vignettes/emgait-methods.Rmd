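---
title: "Methods: gait-cycle EMG analysis under spinal cord stimulation"
author: "emgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-cycle EMG analysis under spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgait)
```

## The analysis problem

Surface EMG recorded while a person walks with transcutaneous spinal cord
stimulation (tSCS) — optionally inside a powered exoskeleton — is heavily
contaminated: a periodic biphasic stimulation artifact at the stimulation
frequency (30 Hz here) and all of its harmonics, 50 Hz power-line
interference, and motion/cable transients from the robot. The scientific
question is whether stimulation changes muscle activation, asked by
comparing per-gait-cycle amplitude metrics between a walking block recorded
*before* stimulation (OFF-PRE) and one recorded *after* it (OFF-POST), with
the stimulated block (ON) in between. Each block lasts 3 minutes; walking is
very slow (gait cycles around 4.5 s), and no external gait events (foot
switches, IMUs) are available, so gait cycles must be segmented from the EMG
itself.

`emgait` implements that full chain — preprocessing, envelope extraction,
EMG-based gait-cycle segmentation, per-cycle RMS and iEMG, and rank-sum
pre/post statistics — and pairs it with a ground-truthed simulator so every
stage is testable with known truth.

## Preprocessing chain

Stages, applied in this order, all IIR filters zero-phase
(forward–backward, so the effective order doubles and no stage introduces
phase lag that would skew cycle timing):

1. **Band-pass**, 2nd-order Butterworth, 20–500 Hz: the standard surface-EMG
   analysis band.
2. **Notch** at 50 Hz: a pole-zero notch (zeros on the unit circle at the
   line frequency, poles at radius $r$ on the same angles).
3. **Stimulation-harmonic comb**: one such section per harmonic
   $k f_{stim} < f_s/2$ (34 sections at 30 Hz and $f_s = 2048$ Hz). Zeros
   sit exactly on the unit circle, so the designed gain at every harmonic is
   identically zero; each section's gain is normalised at the frequency
   midway to the next harmonic so inter-harmonic EMG passes at unit gain.
   The comb is applied only to blocks that actually contain stimulation (ON,
   configurable), and block-wise filtering borrows true neighbouring samples
   as padding so block edges do not excite avoidable transients.
4. **Envelope path**: full-wave rectification, a 0.1 s running median (which
   suppresses impulsive residuals — stimulation remnants, cable/robot
   transients — without blunting the burst shape), then a 2nd-order
   Butterworth low-pass at 1 Hz.

Two numerical choices deserve emphasis:

* **Pole radius.** The 3 dB width of a pole-zero notch is approximately
  $f_s (1 - r)/\pi$. The default $r = 0.9985$ gives ≈1 Hz notches at
  2048 Hz — narrow enough that a 34-section comb leaves inter-harmonic EMG
  essentially untouched (envelope correlation > 0.99 on artifact-free
  data). A notch this narrow rings for $\tau \approx 1/(f_s(1-r)) \approx
  0.3$ s, which is why filters are padded by ~5 ring time constants and
  why steady-state suppression is the meaningful figure of merit at block
  edges.
* **Median placement.** The running median is applied to the *rectified*
  signal inside the envelope path. A 0.1 s median applied to the signed
  wide-band signal would annihilate it (the median of a zero-mean
  oscillation over 200 samples is ≈ 0); on the rectified signal the same
  window is a robust local amplitude estimator. Amplitude metrics are
  computed from the pre-rectification comb-filtered signal, so this choice
  affects only segmentation and visualisation.
* **Cadence adjustment.** The envelope cutoff is
  $\max(1\,\mathrm{Hz}, \text{cadence})$: at the very slow cadences this
  analysis targets (≈0.22 Hz) the 1 Hz default already preserves more than
  one envelope oscillation per cycle, and the rule guarantees that property
  if cadence ever exceeds 1 Hz.

## Gait-cycle segmentation

Cycles are segmented from the reference channel's envelope (default
`TiAn_L`, tibialis anterior), decimated to 64 Hz (the envelope carries no
content above a few Hz; 64 Hz keeps timing quantisation at ±8 ms).

1. **Template bootstrap** (`derive_template()`): the cycle period is the
   envelope autocorrelation peak nearest the expected period (searched in
   `[0.5, 2] ×` expected). Coarse cycles are then extracted as period-length
   windows centred on the per-cycle envelope peaks, and the template is
   their pointwise median. Peak-centred extraction matters: with 10%
   cadence jitter the cycle phase performs a random walk of several seconds
   across a 3-minute block, so a fixed-period fold smears to a flat
   profile, while peak-aligned windows stay sharp.
2. **Anchoring convention**: the template is rotated to start at its peak.
   The burst *centre* is the only landmark invariant to symmetric
   (zero-phase) smoothing — edge landmarks such as threshold crossings or
   half-rise points migrate outward as the envelope is smoothed, which in
   development biased event times by ~90 ms. Cycles are therefore delimited
   peak-to-peak of the reference muscle. For tibialis anterior, whose
   activity rises through terminal swing and peaks at initial contact, this
   is the heel-strike convention; the simulator's reference muscle encodes
   the same timing.
3. **Subsequence DTW matching** (`segment_cycles_dtw()`): the template is
   matched along the envelope by subsequence dynamic time warping (free
   start and end, symmetric steps, per-path Sakoe–Chiba band of half-width
   `0.25 ×` template length, implemented in C++ with start-column
   propagation so no backtracking is needed). Local minima of the
   path-length-normalised cost are accepted greedily, best first,
   non-overlapping; matches whose warped length falls outside
   `[0.7, 1.3] ×` the template length are rejected.
4. **Sub-sample refinement**: within each accepted match the template is
   rescaled to the match's duration and cross-correlated around the DTW
   start (±15% of the template length), with parabolic interpolation of the
   correlation peak. Rescaling first removes the bias a fixed-length
   matched filter acquires on stretched or compressed cycles.
5. **Representative-cycle selection** (`select_cycles()`): a cycle is kept
   iff its length-normalised envelope correlates with the template at
   ≥ 0.7 *and* its duration lies within ±30% of the median duration. This
   replaces the visual inspection a human rater would perform with a
   reproducible rule; if fewer than 10 cycles survive, an explicit
   under-count flag is raised rather than failing.
6. **Normalisation** (`normalize_envelopes()`): selected cycles are
   resampled to 101 points (0–100% of the gait cycle) and divided by the
   mean of the per-cycle peaks — for plots and QA only; amplitude metrics
   are never computed from normalised envelopes.

Segmentation quality is scored against known events by greedy one-to-one
matching within 150 ms (`evaluate_segmentation()`), reporting F1 and the
RMS timing error of matched pairs. The 150 ms tolerance is far below the
4.5 s cycle but comfortably above the timing error a sound segmenter
produces at these noise levels.

## Per-cycle metrics and statistics

For every selected cycle and every channel (reference-channel boundaries
propagate to all muscles, so every muscle shares one cycle definition):

* **RMS** of the comb-filtered wide-band signal within the cycle — the
  activation level;
* **iEMG**, the trapezoidal integral of the rectified signal over the cycle
  (units × s) — the effort generated. Duration is deliberately *not*
  divided out, so iEMG inherits cycle-duration variability; under cadence
  jitter it is intrinsically noisier than RMS.

OFF-PRE and OFF-POST cycle values are compared per channel and metric with
a two-sided Wilcoxon rank-sum test (exact enumeration when the pooled
sample is ≤ 20 without ties, normal approximation with tie and continuity
corrections otherwise), sessions never pooled, the ON block never tested.
Percent change is `100 (mean_post − mean_pre)/mean_pre` (median optional).
No multiple-testing correction is applied by default — the design this
mirrors reports uncorrected p < 0.05 — but Holm adjustment is available
(`adjust = "holm"`). Treating cycles as independent observations is a
documented simplification: consecutive cycles from one subject are not
independent, so p-values are anti-conservative at the subject level.

## The simulator and what it does (not) show

`generate_recording()` produces the three annotated blocks with, per
channel: one raised-cosine activation burst per cycle (onset/duration as
cycle fractions, typical gait timing for 7 SENIAM muscles × 2 sides)
amplitude-modulating a 20–450 Hz noise carrier; 50 Hz line interference
(amplitude 0.2 relative to a unit burst); Gaussian background noise
(SD 0.1); sparse < 10 Hz damped-sinusoid motion transients (2/min,
amplitude 1); and, during ON only, a symmetric biphasic rectangular pulse
train (1 ms per phase, 30 Hz, amplitude 10 — transcutaneous stimulation
artifacts dwarf microvolt-scale EMG). Cycle periods jitter multiplicatively
(SD 10%, clamped at ±4 SD); `effect_map` scales named channels in OFF-POST
by `1 + fraction`, and all cycle-start, pulse and effect ground truth is
returned. One seed ⇒ bit-identical output.

The defaults are the study conditions the package is validated under:
180 s blocks, 4.5 s cycles, 10% jitter. At these settings the packaged
benchmarks (20 seeded trials; `segmentation_benchmark()`) yield mean
F1 ≈ 0.97 at 150 ms tolerance and mean timing RMSE ≈ 55 ms, and a +10%
injected OFF-POST amplitude effect is recovered within ±2 percentage
points and flagged significant in ≥ 95% of 50 seeded runs while null
channels stay at the nominal false-positive rate.

What the simulator does *not* model — and hence what passing tests cannot
certify about real data: physiologically evoked responses to stimulation
(the artifact is purely additive and exogenous), amplifier saturation,
electrode-skin impedance drift, muscle fatigue within a block, double-burst
or absent-burst activation patterns in impaired gait, and correlated noise
across channels. Real recordings from clinical populations are harder than
this simulation in all of those ways; the simulation's role is to verify
the machinery, not to estimate clinical performance.

## Problem sizes and runtime choices

Unit tests run on 12–60 s recordings with 2 of the 14 default channels;
the performance benchmarks use the full 180 s × 4.5 s-cycle conditions
with the reference channel only (for the first channel of the montage this
is sample-identical to simulating the full montage under the same seed).
Statistical calibration uses 200 null replicates (type-I error) and 50
seeded end-to-end runs (effect recovery). The subsequence-DTW cost scan and
the comb's second-order-section cascade are the two compute-critical
kernels and are implemented in C++.

## Known limitations

* Cycles are defined peak-to-peak on one reference muscle; if that muscle's
  activity is absent or grossly abnormal, segmentation degrades — the
  under-count flag and selection reasons surface this rather than hiding it.
* The exact rank-sum path requires tie-free data; measured floating-point
  metrics essentially never tie, but heavily quantised inputs would silently
  use the corrected normal approximation.
* Percent change is computed from block means of cycle metrics; with < 10
  cycles per block it is a noisy estimator, which is precisely why the
  10-cycle rule exists.
* Because iEMG integrates over the cycle duration, any between-block
  difference in realised cadence shifts iEMG coherently even when
  amplitude is unchanged: in simulation with 10% cadence jitter, null
  channels show "significant" iEMG differences well above the nominal rate
  while RMS stays at it. An iEMG difference should therefore be read
  together with the cycle durations (reported per cycle in the metrics
  table) before being attributed to activation change.
* The comb filter's zeros remove genuine EMG power in ±0.5 Hz slivers
  around each harmonic; with ≈1 Hz notches this is < 2% of the 20–500 Hz
  band, but it is not zero.
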