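---
title: "Methods: noise-calibrated astrocytic Ca2+ event detection and sleep-wake analysis"
author: "roawake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise-calibrated astrocytic Ca2+ event detection and sleep-wake analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roawake)
```

## The problem

Astrocytes produce Ca2+ transients spanning four orders of magnitude in
size — from sub-micron microdomains in fine processes to waves covering a
whole field of view — and their rate is strongly modulated by behavioral
state. Static, hand-drawn ROIs miss most of this activity because events
rarely recur at fixed locations. `roawake` implements an activity-based
alternative: every voxel of a two-photon movie is tested against its own
noise level, and contiguous supra-threshold voxels in x-y-t are aggregated
into *regions of activity* (ROAs), each with a start time, spatial
footprint (µm²), duration (s) and volume (µm²·s). Around this core the
package provides the companion machinery needed to relate events to brain
state: rule-based sleep-wake scoring from ECoG/EMG/motion, microarousal and
sleep-spindle detection, transition-locked onset statistics, a
state-specificity test for activation maps, conventional ROI trace
analysis, and a synthetic-data generator that makes every stage testable
against ground truth.

## The ROA detection model

Let `F(x, y, t)` be the motion-corrected movie after per-frame Gaussian
smoothing (`sigma` = 2 px). The processing chain is:

1. **Baseline.** A centered moving average of width `w` = 1.0 s
   (`L_filt = round(w * frame_rate)` frames) gives a lowpass series
   `F_LP`; the per-pixel histogram **mode** of `F_LP` over time is the
   baseline image `F0`. The mode is used rather than a mean or median
   because Ca2+ transients are sparse and strictly positive: most samples
   sit at baseline, so the mode is insensitive to activity.
2. **dF/F0.** `S = (F - F0) / F0`.
3. **Noise.** `S_LP` = moving average of `S` (width `w`);
   `S_HP = S - S_LP` is noise-dominated, and since an `L`-point average
   reduces white-noise SD by `sqrt(L)`, the per-pixel noise SD of `S_LP`
   is estimated as `sigma(x, y) = SD_t(S_HP) / sqrt(L_filt)`.
4. **Drift removal.** `S_BP = S_LP - movingaverage(S_LP, 10 s)` removes
   slow fluorescence drift.
5. **Thresholding.** A voxel is active when `S_BP > k * sigma` with
   `k = 5` (strictly one-sided: Ca2+ indicators report activity as
   fluorescence increases). Vessel/artifact pixels supplied as an ignore
   mask are never active.
6. **Events.** Adjacent active voxels (default 26-connectivity in x-y-t,
   configurable to 6) form one ROA; descriptors are the start frame, the
   duration between first and last active frame, the footprint (union of
   active pixels over the event's lifetime, by default; the maximal
   instantaneous area is available via `footprint = "max_frame"`), and the
   volume `n_voxels * pixel_area / frame_rate`.

For pure Gaussian noise the one-sided exceedance at `k = 5` is about
`3e-7` per voxel, so an hour-long 512 x 512 movie contributes only a
handful of false-positive voxels; the detector's specificity is verified
on pure-noise movies in the test suite. Raising `k` can only shrink the
active set (monotonicity), and event voxel counts always partition the
active voxels (conservation); both are asserted as properties.

### Numerical choices

* Moving averages use shrinking windows at the recording edges (output
  length preserved); edge frames are flagged. An even filter length is
  half a sample asymmetric — on a linear ramp the detrended interior is
  `slope/2`, not exactly zero.
* The mode estimator uses 100 equal-width bins spanning the 0.1–99.9
  percentile range of each pixel's lowpass trace (bin count configurable);
  tests compare it with a dense-histogram oracle.
* Spatial smoothing pads by edge replication. Circular (FFT wraparound)
  padding is unacceptable here: it copies event mass from one border of
  the field to the opposite border and creates ghost detections.
* Baselines are floored at the 1st percentile of the positive `F0` values;
  the number of floored pixels is reported.
* The sigma image is computed over the full recording (not per episode).
* Connected-component labeling is compiled (Rcpp) flood fill; 100 random
  masks per run are checked against a plain-R oracle.

### What the method does not do

There is no spatial deconvolution: co-active overlapping events merge into
one ROA. This matters at high event density — in validation the wake-state
event count is measurably depressed by merging when several events are
co-active — and is the reason the recovery studies below use moderate
densities. Single-plane imaging only; motion correction is assumed done.

## Synthetic sessions

`simulation_config()` + `generate_session()` produce a movie with known
events and matching physiology:

* **Events** are isotropic spatial Gaussians (sigma 4 µm by default) with
  a linear rise over the first 20% of their duration and an exponential
  decay, placed by a Poisson process whose rate (events/100 µm²/min) is
  state-dependent. Default rates fall several-fold from wakefulness to
  sleep (locomotion 4, whisking 2, quiet 1, NREM/IS 0.23, REM 0.35),
  mirroring the strong wake-over-sleep contrast this class of experiment
  reports. Amplitude defaults to 1.0 dF/F0 against a noise floor of 0.05
  (baseline 100 a.u., Gaussian noise SD 5 a.u.); durations are uniform on
  0.5–3 s. Event counts are governed by the non-vessel (sampled) area so
  configured rates match downstream per-area frequency estimates.
* **Ground truth** records each event's placement, half-max footprint and
  frames. For morphology-recovery studies the generator can also return
  the noiseless movie: running the detection chain on it (with the noisy
  run's sigma map, i.e. the same threshold) yields a measurement-referred
  reference, since the active support at `k * sigma` is a threshold level
  set — roughly 3x the half-max area at 8x SNR — and comparing the noisy
  result against the raw generative footprint would conflate the
  measurement model with noise effects.
* **ECoG** is a sum of Butterworth-band-limited noise (delta 0.5–4, theta
  5–9, sigma 10–16, beta 16–30 Hz) with state-specific weights chosen so
  the standard scoring definitions hold by construction: NREM
  delta-dominant, REM theta/delta well above 0.5 with minimal muscle
  tone, IS with elevated sigma/theta and reduced delta, wakefulness
  desynchronized with high EMG. Spindles are Hann-windowed 12–14 Hz
  sinusoids (0.5–2 s, amplitude 2x the NREM ECoG RMS) inserted during IS
  at a Poisson rate (default 4/min). EMG is 100+ Hz band noise with
  state-dependent tone; wheel/snout traces carry above-threshold motion
  during locomotion/whisking, plus brief (0.5–2.5 s) snout bursts inside
  NREM that serve as ground-truth microarousals.
* Physiology is generated at 500 Hz by default. The EMG band is capped at
  45% of Nyquist, so the nominal 100–1000 Hz EMG range is represented as
  100–225 Hz; scoring uses only the RMS tone, which this preserves.

What the generator does **not** emulate: GCaMP kinetics (the temporal
profile is phenomenological), motion artifacts, vessel pulsation,
electrode artifacts, real spindle waxing-waning morphology, and the
long-tailed event-size distributions of real astrocytes. Passing recovery
tests therefore demonstrates internal consistency of the pipeline under
its stated noise model, not performance on real recordings.

## Sleep-wake scoring

Scoring is rule-based on 1 s epochs (epoch length is a package choice; a
3-epoch majority vote smooths single-epoch flicker). Band powers and EMG
RMS are first smoothed with a 5-epoch centered moving average — 1 s
periodogram band estimates have few degrees of freedom and are noisy.
Rules, in order:

1. **Wake** when the EMG RMS exceeds the geometric midpoint of its 10th
   and 90th percentiles, or when wheel/snout motion is above threshold.
   If the EMG RMS distribution is unimodal (90th/10th percentile ratio
   < 2) the recording has a single muscle-tone regime and EMG is treated
   as uninformative; wake then comes from motion alone. Wake sub-states:
   locomotion (wheel above threshold, taking precedence, since locomotion
   includes whisking), whisking (snout only), quiet (neither).
2. **IS** for sleep epochs whose sigma-band fraction of total power
   exceeds 0.17 (between the generator's NREM ~0.08 and IS ~0.31;
   spindle-band elevation is what distinguishes IS from REM even when
   theta/delta is high).
3. **REM** for remaining sleep epochs with theta/delta > 0.5 and low EMG.
4. **NREM** otherwise.

Wake intrusions shorter than 3 s flanked by sleep stay in the host sleep
state — by the standard microarousal definition these are not state
changes. Sleep episodes of 30 s or less are flagged `excluded`. On
generated sessions the scored hypnogram agrees with the truth at 97–99%
per second; the acceptance suite requires at least 90% across 20 seeds.
All thresholds are relative to per-recording statistics (scale-invariant)
and exposed in `score_thresholds()`; the defaults were tuned on the
generator.

Awakening onsets can be refined from the scored boundary by an automated
surrogate for ECoG desynchronization: scanning from 5 s before the
boundary, the first 1 s window whose delta power falls below 50% of the
preceding episode's median. Refined rows are flagged — the original
analysis did this step by eye, and the surrogate is this package's
automation.

## Sleep spindles

The normalized ECoG is bandpass filtered at 10–16 Hz (second-order
zero-phase Butterworth via forward-backward filtering), the instantaneous
amplitude is taken from the Hilbert analytic signal and smoothed with a
0.2 s Gaussian; above-threshold envelope peaks are candidate spindles and
candidates whose width at the threshold level is below 0.5 s or above 5 s
are discarded. (The sigma band is 9–16 Hz in some scoring conventions;
the band edges are arguments.)

The amplitude threshold is the one free parameter. The default is
median + 2.5 x MAD of the smoothed envelope *within the scored episode*.
MAD rather than SD: the spindles themselves inflate an SD estimate, so an
SD-based threshold would rise with spindle density; the MAD estimates the
background envelope scale. Detection near the detectability floor is
intrinsically limited by the width rule: a 0.5 s burst whose envelope
peaks at ~2x the background median (~6 dB) is above threshold for less
than 0.5 s at any threshold that controls the background false-positive
rate, and is discarded by the width rule. On generated IS sleep, recall
is 1.0 for spindles with >= 8 dB smoothed-envelope SNR, ~0.9 at >= 6 dB,
with precision ~0.95; sub-width (0.3 s) and out-of-band (25 Hz) bursts
are rejected exactly.

## Transition-locked dynamics

ROA frequency traces (events per 100 µm² per minute, counted by start
frame) are smoothed with the causal kernel `k(t) = t * exp(-t / tau)`
(`tau` = 0.25 s, unit-normalized). A symmetric kernel would leak activity
backward in time and bias onset estimates early; this kernel is exactly
causal (`k(0) = 0`, implemented by direct time-domain convolution so the
pre-impulse response is exactly zero) and peaks at `t = tau`, so the
smoothing lag is bounded by ~`tau`. Traces in a −15..+15 s window around
each transition are z-scored by the mean and SD of the −15..−5 s baseline
segment; rows with zero baseline SD are excluded and counted. Onset is
the first crossing of 2.5 (baseline SDs), scanning forward from −5 s —
the scan starts at the end of the baseline window so baseline noise is
not trivially detected. Peaks are row maxima. On 100 synthetic
transitions with a rate step 1.5 s before the boundary the mean estimated
onset is within the smoothing lag of −1.5 s.

Astro-neuron coupling is summarized by the maximal Pearson
cross-correlation over lags within ±2 s (both traces Gaussian-smoothed,
sigma 0.25 s). The small lag range suffices because observed lags are
below one frame; it is configurable.

## Activation-map overlap and PERMANOVA

Per-episode activity heatmaps (fraction of active frames per pixel) are
compared with the Jaccard similarity
`J(x, y) = sum min(x_i, y_i) / sum max(x_i, y_i)`; `d = 1 - J` is the
distance. For one field of view with at least 8 episodes, PERMANOVA tests
whether episodes of the same state are more similar than episodes of
different states: the distance matrix is Gower-centered, sums of squares
are partitioned sequentially with the per-episode mean activation entered
*before* the state factor (the state effect is conditional on overall
activation level), and the p-value is `(1 + #{F* >= F}) / (1 + n_perm)`
under free permutation of state labels (999 by default; residual
permutation after removing the covariate projection is available via
`permutation = "residual"`). The implementation is cross-checked against
an independent PERMANOVA implementation (vegan) to equality of SS, F and
R² in the tests; its type-I error is 0.05 ± 0.03 under a permuted-label
null, and on perfectly state-specific geometry (12 episodes, 3 states) it
returns the minimal p `1/(n_perm + 1)` with R² near 1. With small
balanced designs note that label permutations can reproduce the original
partition, which puts a combinatorial floor on the attainable p-value.
Results can depend on the distance choice; no multiple-comparison
correction is applied across FOVs.

## ROI trace analysis

For hand-drawn ROIs (circles, polygons, 5 µm doughnut annuli around
neuron somata, auto-placeable 5 µm neuropil circles at 5 µm clearance),
traces are per-frame means; `F0` is the trace mode; neuronal traces are
neuropil-corrected as `(F_neuron - F_doughnut) / F0`. Events are detected
on the Gaussian-smoothed trace (sigma 0.25 s astro / 0.1 s neuron) after
subtracting a heavily smoothed (sigma 120 s) drift trace, at 2.5x (astro)
or 2x (neuron) the SD of the noise trace (raw minus smoothed; the
trace-level SD is used directly, without the `sqrt(L)` correction of the
voxel pipeline). Onset is defined at the threshold crossing, duration
between the surrounding zero crossings, amplitude as the in-event peak.
Onset-difference histograms (1 s bins) collect astro onsets around each
neuronal event. On synthetic movies with microdomain events scattered
outside somata, ROA detection finds several-fold more events than
soma-ROI traces — the qualitative contrast that motivates the
activity-based method; the exact factor is data-dependent.

## Validation problem sizes

The standard validation settings (test suite and `scripts/acceptance.R`)
are: 128 x 128 x 3000 pure-noise movies for specificity; 64 x 64 x 3600
at 8x noise amplitude for recovery; 100 random 16 x 16 x 20 masks for the
component-labeling oracle; 200 null datasets x 999 permutations for
PERMANOVA size; 20 seeds of a ~9-minute six-state schedule for scoring
recovery; ten 2-minute IS segments for spindles; 100 transitions for
onsets; and three pooled 300 s two-state sessions at a 0.23 sleep:wake
rate ratio for end-to-end recovery (counting noise ~3 percentage points,
1 SD, on the 77-point reduction). These sizes keep counting noise well
inside the stated tolerances while remaining desk-scale.

## Known limitations

* No spatial deconvolution of merged events; frequency estimates compress
  at high densities.
* Mode baselines assume activity is sparse in time; continuously active
  pixels bias `F0` upward.
* Scoring thresholds were tuned on the generator's spectra; real
  recordings will need threshold review (all are exposed).
* The spindle width rule bounds recall near the 6 dB envelope-SNR floor
  (see above).
* TIFF output stores 32-bit scaled samples: round trips are exact to
  ~2^-32 relative, not bit-identical.
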