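---
title: "Quantifying neurovascular reactivity with nvckit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurovascular reactivity with nvckit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvckit)
```

`nvckit` quantifies two complementary views of neurovascular
reactivity: the regional cerebral blood flow (CBF) response seen by
laser speckle contrast imaging (LSCI), and single-vessel dilation seen
by two-photon microscopy (2-PM). This vignette explains the model
behind each pipeline, every tunable that matters, the numerical
choices, and what the synthetic-data validation does and does not
demonstrate.

## The LSCI response model

LSCI reports perfusion in arbitrary units; all quantities are therefore
ratios. For a stimulation epoch with onset $t_0$, the per-pixel
response is

$$\%\Delta = 100\cdot\frac{\bar P_{[t_0+10,\,t_0+30]} -
\bar P_{[t_0-40,\,t_0-10]}}{\bar P_{[t_0-40,\,t_0-10]}}$$

The response window starts 10 s after the onset so that a ramp-like
initial rise of perfusion does not dilute the plateau estimate; the
baseline window ends 10 s before the onset so that anticipatory or
threshold-straddling samples never contaminate the baseline. Both
windows are `response_windows()` parameters (seconds relative to
onset; defaults `c(10, 30)` and `c(-40, -10)`).

Because the response is normalized to a *local, per-epoch* baseline,
slow drift (anesthesia depth, physiological state) cancels to first
order in the maps, and any multiplicative rescaling of the signal
cancels exactly — the test suite asserts bit-level invariance of every
output under stack rescaling.

### Drift filtering and onset detection

Epoch detection needs a trace without drift. The ROI-mean trace is
filtered with a high-pass Chebyshev Type I design (`drift_filter()`:
order 2, passband edge 0.004 Hz, 0.5 dB ripple), applied forward and
backward (`filter_trace()`) so the net phase is zero and onsets are not
displaced. Two implementation details matter at such a low cutoff
(the filter time constant is ~4 min of samples):

* the filter state is initialized to its step-response steady state, so
  a constant trace maps to numerically zero (measured residual
  ~1e-22 of the input level) rather than producing a large edge
  transient;
* the trace is extended by odd reflection over six filter time
  constants (clipped to the trace length) before filtering, which keeps
  the response to a centered symmetric pulse symmetric to <1e-9.

The forward–backward application squares the magnitude response; the
passband therefore ripples within $[(1+\varepsilon^2)^{-2}, 1]$ with
$\varepsilon^2 = 10^{R_p/10}-1$. The ripple default (0.5 dB) is a
conventional engineering choice; response amplitudes are computed on
raw traces (below), so they are insensitive to it.

Onsets are found by Otsu's method (`otsu_threshold()`): a 256-bin
histogram of the filtered trace, split at the bin edge maximizing the
between-class variance. Maximal supra-threshold runs become epochs
after bridging sub-threshold gaps shorter than 2 s and discarding runs
shorter than 5 s (both configurable); these two defaults suppress
noise chatter around threshold crossings while preserving the 60-s
stimulations the protocol uses. A zero-phase-filtered step keeps a
sharp jump at the true onset, and the Otsu threshold falls in the gap
between the baseline and stimulated value clusters, so the first
supra-threshold sample lands within ±1–2 samples of the true onset.
Otsu is degenerate on (near-)constant traces — detected by a
between-class variance below 1e-10 of the trace variance — and the
function then returns no epochs with a warning. A genuinely noisy but
unimodal trace still yields a split (this is inherent to Otsu); the
pipeline therefore always emits a detection-verification plot
(`plot_detection()`), mirroring the visual check that is standard
practice with automatic detection. For CO₂ challenges the 5-min
inhalation window is usually known from the capnograph; external event
markers (`epochs_from_markers()`) then take precedence over detection.

### Raw vs. filtered traces: where each is used

The high-pass filter distorts a 60-s boxcar substantially (its time
constant is comparable to the stimulus duration), so it must *not* be
applied before amplitude estimation. The pipeline therefore:

* detects epochs on the **filtered** ROI-mean trace (drift would
  otherwise move the Otsu threshold);
* computes per-pixel map amplitudes on the **raw** stack, normalized to
  the per-epoch local baseline (which cancels drift over the ~45 s
  separating the window centers to first order);
* computes the scalar peak/slope/AUC metrics on the **filtered**
  ROI-mean trace scaled by the raw per-epoch baseline level. Computed
  on the raw trace these metrics would inherit a drift term of (drift
  slope × 45 s) — about 1.5 % under a 20 %/10 min drift — whereas on
  the filtered trace they change by <0.5 % under the same drift (a
  property the suite tests). The filter's boxcar distortion affects
  added drift and signal identically, so this choice trades a small,
  *constant* shape bias for drift immunity; peak amplitudes against
  ground truth are validated on the maps, not on the scalar trace
  metrics.

### Alignment, standardization, averaging

Heartbeat and breathing shift frames by a few pixels.
`align_frames()` estimates one integer translation per frame by
FFT cross-correlation against the pixelwise median frame (search
radius 10 px, configurable, off by default for the drift-stable
synthetic data), and flags exposed borders missing. Alignment
confidence is reported: shifts on the search boundary or with peak
correlation <0.2 warn, since featureless frames cannot be registered.

Native-resolution maps are cropped to the square bounding box of the
circular ROI and resampled to 120 × 120 with bilinear interpolation
under the half-pixel-center convention (`bilinear_resize()`), making
maps comparable across animals with different window sizes. The
resampler is written in-package for two reasons: missing values
(outside-ROI, non-positive baselines, alignment borders) must propagate
deterministically — any output pixel touching a missing input pixel is
missing — and constants must resample exactly (nested-lerp form), so
that averaging maps is order-invariant in exact arithmetic.
Averaging (`average_maps()`) is the pixelwise mean over available
values, first across the stimulation repetitions of one animal, then
across animals; counters of both are carried on the result. Pixels
missing in every input stay missing rather than silently becoming
zero.

Heat maps use a fixed 0–15 % color scale by default so that images from
different groups are directly comparable; the numeric matrix is always
exported alongside the PNG at full precision.

## The vessel diametry model

2-PM movies show plasma fluorescence: the vessel lumen is bright, the
wall and tissue dark. Frames are smoothed (Gaussian, σ = 1 px) and
binarized per frame with Otsu's threshold; per-frame thresholds adapt
to photobleaching, and a fixed-threshold mode exists when strict
cross-frame comparability is preferred. Smoothing happens only before
binarization; diameters are always counted on binary frames.

For a measurement line drawn across the vessel, `measure_diameter()`
samples the segment at unit arc-length spacing, maps samples to nearest
voxels, counts lumen voxels and multiplies by the voxel size. Sampling
by arc length (rather than a per-axis pixel walk) keeps the estimate
correct for oblique lines: a pixel walk visits ~max(|Δr|,|Δc|) cells
and would undercount a 45° chord by √2, while arc-length sampling
recovers 45° tubes within 1.5 voxels (measured: 0.5). Axis-aligned
tubes of widths 3–30 voxels are recovered exactly.

The line thickness default of 4 means four parallel lines at unit
perpendicular spacing (offsets −1.5, −0.5, +0.5, +1.5 voxels; for
general *k*, *k* symmetric half-integer offsets) whose diameters are
averaged. Erythrocytes passing through the lumen transiently darken
single voxels; on one of four lines such a gap biases the mean by only
1/4 voxel instead of a full voxel.

### Baseline-tracking peak detection

`detect_peaks()` walks the diameter trace as a state machine with
three user-facing parameters (`peak_params()`):

1. **baseline**: mean of the next `n_baseline_frames` (10) valid
   frames; its timestamp is the last frame entering the mean — the last
   timepoint before detection resumes — which is what the slope formula
   divides by;
2. **open**: first frame exceeding baseline × (1 + 5 %);
3. **close**: after `min_end_frames` (3) consecutive valid frames below
   baseline × (1 + 2 %). The hysteresis (close threshold below open
   threshold, plus the debounce count) prevents chatter on noisy
   plateaus. A trace that ends mid-peak closes the peak at the last
   frame;
4. after a close, the baseline is recomputed immediately from the
   following frames and detection continues. (A configurable refractory
   gap was considered and rejected: immediate recomputation is the
   simplest rule consistent with tracking slow baseline drift between
   events, and the brute-force reference implementation in the test
   suite pins this behavior frame-for-frame.)

Excluded frames are skipped everywhere (they neither enter baselines
nor open/close peaks). Each peak reports
`percent_change = 100 (d_max − d_base)/d_base` and
`slope = ((d_max − d_base)/(t_max − t_base))/d_base`; both identities
are asserted to machine precision on every emitted peak. Ties for the
maximum take the earliest frame. A non-positive baseline (possible
only on pathological binarizations) skips the segment with a warning;
a peak whose maximum coincides with the baseline timestamp has an
undefined slope (`NA`).

Artifact frames (heavy motion, low SNR) are the user's call — as in
any interactive workflow — but `flag_artifact_frames()` makes
suggestions: a frame that decorrelates (Pearson r < 0.8) from *both*
neighbors (so a single jittered frame flags itself, not its innocent
successor), or whose foreground-mean to background-SD ratio after a
provisional Otsu split falls below 2. User-listed exclusions are always
unioned in.

## The synthetic generators

`simulate_lsci()` renders per-pixel perfusion
$P = P_0\,(1 + d(t) + b(x,y)\,r(t))(1+\epsilon)$ with a linear or
sinusoidal drift $d$, a Gaussian spatial response blob $b$ (maximum 1),
a ramp-then-boxcar time course $r$, and multiplicative Gaussian noise
$\epsilon$ — speckle noise is signal-proportional, which multiplicative
noise captures without modeling optics. Defaults emulate the standard
protocol: three 60-s stimulations at 120-s intervals (onsets 120, 300,
480 s) at 4.4 Hz, baseline 500 a.u., 10 % amplitude, blob σ 15 px,
3 % noise, 5 %/10 min linear drift. The default onset ramp is 0 s: a
threshold detector crosses a ramped onset at roughly half the ramp
duration, so the sharp default separates onset-accuracy validation from
ramp effects; ramped configurations are used where the window logic
itself is under test.

`simulate_vessel()` renders an anti-aliased tube of width
$w(t) = w_0(1 + \text{dilation}(t)/100)$ with coverage-weighted edge
voxels, optional dark intraluminal discs (Poisson-placed erythrocytes),
optional jittered frames, and additive Gaussian noise (5 % of the
dynamic range by default — fluorescence noise is closer to additive at
these intensities). Defaults: 270 frames at 2 s/frame (the typical
series length), width 40 voxels, intensity 200 on background 10,
dilations of 10 % at frames 30/120/210. The tube axis lies on a pixel
boundary and the default widths and amplitudes give even plateau
widths, so the true plateau diameter maps to an exact voxel count;
recovery tolerances then measure the pipeline, not rasterization
phase. Both generators are pure functions of their configuration
(seed included).

**What passing these tests shows — and what it does not.** The
generators emulate the *geometry and statistics* the pipeline depends
on: drifting baselines, threshold-crossing onsets, blob-shaped
responses, edge-quantized tube widths, erythrocyte shadows, motion
artifacts. They do not emulate real speckle statistics, vessel
curvature or branching, focus drift, or neurovascular response shapes
beyond ramp/boxcar. Recovery of known amplitudes within 1 percentage
point therefore validates the computational chain, not the biology; on
real data the visual verification artifacts (detection plot, overlay
image) remain part of the workflow.

## Problem sizes and runtime choices

The test suite runs the full three-stimulation LSCI protocol (2904
frames, 4.4 Hz) on 48 × 48 fields, three animals per amplitude for
amplitudes 5/10/15 %, and vessel movies of 120 frames at 128 × 128 for
dilations 5/10/20 % — small enough for a ~20 s suite while exercising
every stage at full temporal resolution. `scripts/acceptance.R` re-runs
the same computations from scratch. Peak-detector equivalence against
an independently written brute-force scan is checked on dozens of
randomized traces up to 300 frames, and Otsu detection against
exhaustive between-class-variance search on 100 randomized traces.

## Known limitations

* Alignment is integer-pixel and rigid; sub-pixel or rotational motion
  is not corrected.
* Otsu detection assumes the stimulated state is visible in the trace
  histogram; weak responses (comparable to noise) need event markers.
* Diameters are 2-D: the measurement plane is assumed to cut the vessel
  perpendicularly; out-of-plane tilt inflates diameters by 1/cos(tilt).
* The scalar slope is a two-point estimate (peak minus baseline over
  elapsed time), chosen to match the vessel-diametry slope definition,
  not a fitted rise rate.
* The open raw-binary/TIFF readers expect the documented layouts;
  proprietary vendor containers must be exported to open formats first.
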