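---
title: "widecal: models, parameters and validation of the wide-field calcium pipeline"
author: "widecal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{widecal methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`widecal` turns a raw wide-field single-photon calcium movie into per-neuron
fluorescence traces and task statistics in a fixed sequence of stages:
contrast enhancement and rigid motion correction; per-pixel statistics;
activity-based detection of single-frame regions of interest (ROIs);
clustering of those detections into per-neuron multi-frame ROIs; trace
extraction and dF/F normalization; trial scoring from an eyelid-reflection
trace; trial-aligned task-modulation statistics; and spatial statistics on
the ROI centroids. Because raw recordings of this kind are tens of
gigabytes and rarely shareable, the package ships a simulator that renders
movies with full ground truth (planted somata, transient times, rigid
motion, illumination field, bleaching, trial schedule, modulation labels),
and every stage is validated against what was planted.

This vignette explains the models behind each stage, the tunable
parameters with their defaults and units, what the simulator does and does
not emulate, and the numerical choices that required a decision.

# Motion correction

## Homomorphic contrast enhancement

Illumination non-uniformity is multiplicative and static in the camera
frame, while the tissue moves under it; left in place it anchors any
correlation-based registration at zero shift. `homomorphicEnhance()`
therefore high-passes each frame in the log domain:

    y = exp(L - G(L) + mean(G(L))) - 1,   L = log(1 + x)

with `G` a Gaussian low-pass of width `filterSigma` (default 32 px, about
42 µm at 1.312 µm/px — several times the ~5.7 px soma radius, so somata
pass through intact). Computing the low-pass explicitly and subtracting
avoids the ringing of direct high-pass kernels; adding back the mean of
the low-pass keeps overall brightness roughly unchanged.

The low-pass is a separable Gaussian-weighted *local-linear* smoother,
applied as two precomputed banded matrix products. In the interior this is
exactly a normalized Gaussian kernel; at the frame boundary the
local-linear fit remains exact on linear trends, so an illumination
gradient does not leak into the high-pass residual near the edges (plain
kernel renormalization leaves a percent-level edge band, which is enough
to matter when the goal is a 10-fold flattening of the field).

## Phase-correlation displacement estimation

`estimateDisplacement()` forms the cross-power spectrum of the enhanced
moving frame and the template, normalizes it, inverse-transforms, and
reads the shift off the correlation peak. Both real-frame FFTs are
obtained from a single complex FFT (packing one frame into the imaginary
part), which roughly halves the transform cost of the sequential loop.

The normalization is *regularized* phase correlation:

    R / (|R| + eps * max|R|),   eps = 1e-3 by default.

Pure phase correlation (vanishing `eps`) whitens every spectral bin to
unit magnitude, which makes near-empty bins — bins carrying nothing but
quantization texture of the static illumination field on a noise-free
16-bit movie — vote for zero shift with full weight. On rendered test
movies this inflates the shift error from ~0.08 px RMSE to ~2 px. Any
floor between 1e-6 and 0.1 restores the sub-0.1 px plateau; 1e-3 sits in
the middle of that plateau. A `normalization = "cross"` switch selects
plain cross-correlation weighting for comparison.

The peak search is restricted to shifts of at most `maxShift` (default
25 px) per axis, with exact ties broken toward the smallest shift. With
`subpixel = TRUE` the integer peak is refined by separable 3-point
parabolic interpolation of the correlation surface — interpolation of the
surface, not the image, which is cheap and accurate to ~0.1 px on
band-limited content.

## Template and loop

The template is seeded with the first frame and updated as a running mean
of previously aligned, enhanced frames with effective window
`min(frameIndex + 1, templateWindow)` (default window 50). In
`two_pass_fixed` mode a fixed mean of randomly sampled, individually
aligned frames is first registered to the frame-1 template (so it cannot
shift the anchor) and then blended half-and-half into the running mean at
every update.

All shifts are therefore *relative to the first frame's position*; when
validating against planted motion the ground-truth trace is re-expressed
relative to frame 1. Frames are corrected by shifting the native-depth
frame back by the estimate with bilinear interpolation and replicated
edges (`applyShift()`); integer shifts are exact translations. The
per-frame displacement magnitude in µm (`magnitude = sqrt(dx^2 + dy^2) *
pixelPitch`) is the session motion metric reported in the manifest.

# ROI detection

Each corrected frame is z-scored per pixel against the full-session
per-pixel mean and population SD (`computePixelStats()`, exact two-pass
moments). Zero-SD pixels get z = 0 and are flagged rather than infinite.

`adaptiveThreshold()` starts at `z0 = 1.5` SD and raises the threshold in
0.25 SD steps while more than `activeFracBounds[2]` (default 1%) of the
pixels are active, then lowers it while fewer than `activeFracBounds[1]`
(default 0.05%) are active, clamped to [1, 6] SD with at most 20
iterations. The adjustment exists to keep global brightening or
motion-induced border contrast from flooding a frame with foreground; the
fraction targets are package choices (the adjustment rule itself is part
of the method).

The binary mask is closed then opened with 1-px discs (`EBImage`
morphology), and connected components are labelled with an 8-connected
union-find (implemented in C++; 4-connectivity is available). Components
with areas outside [30, 300] px are discarded — a 15 µm soma at
1.312 µm/px covers ~103 px, so the bounds bracket plausible somata and
reject speckle and border strips. Surviving components become
*single-frame ROIs* with unweighted centroids and half-open bounding
boxes.

# ROI merging

`clusterRois()` merges single-frame ROIs into *multi-frame ROIs* (one per
putative neuron). Two detections are "the same cell" (`roiSimilar()`)
when their centroids are within `centroidTol = 8` px *and* both
bounding-box corners are within `bboxTol = 12` px. Detections are
pre-grouped into overlapping 128-px blocks (32-px overlap) by centroid;
inside each block an incremental single-linkage pass in frame order joins
each detection to the nearest similar cluster (running-mean centroid and
corners), else seeds a new cluster. A redundancy pass then merges
clusters across blocks that satisfy the same similarity rule, so the
result matches an unblocked single-linkage clustering — an equivalence the
test suite checks against an independent reference implementation. An
optional ×2-area bucket prefilter (`sizeBucketing`) accelerates the
candidate search but is off by default because it can split clusters
whose member areas straddle a bucket edge.

The final mask keeps pixels present in at least `maskFreqThreshold = 0.25`
of the contributing frames (a frequency-weighted mask; the union was the
alternative and is recovered with threshold → 0). Clusters seen in fewer
than `minFrames = 5` frames are dropped. The ROI centroid is the mean of
the contributing single-frame centroids.

`filterSeparated()` is the algorithmic surrogate for manual curation of
overlapping cells: while any pair of masks has IoU above `maxIou = 0.3`,
the pair with the largest IoU is resolved by dropping the member with
fewer appearances (ties: smaller area, then larger index). No surviving
pair overlaps above the cap.

# Traces, SNR, photobleaching

`extractTraces()` averages the native-depth corrected movie over each mask
per frame (a sparse matrix product over frame chunks); the 8-bit reduced
copy produced by `reduceBitDepth()` (global 1st/99th percentile clip
mapped to [0, 255]) is for storage and visualization only.

`normalizeTrace()` computes dF/F relative to the whole-trace mean,
`d = (f - f_avg)/f_avg`, then rescales by one positive factor so the
trace maximum is exactly 100 (%). Negative excursions scale by the same
factor; a constant trace maps to zeros. Dividing by the maximum before
multiplying by 100 makes the peak *exactly* 100 in floating point.

SNR per ROI is the maximum raw trace intensity divided by the mean
temporal SD of all pixels not registered to any ROI. Photobleaching is
the percent drop of the whole-field mean from the first to the last frame
(optionally averaging k frames at each end).

# Behavior and task statistics

Trials are a 350 ms tone, a 250 ms trace interval, and a 100 ms air puff
(tone-to-puff 600 ms), with inter-trial intervals drawn uniformly from
31-36 s. A trial is scored *correct* when any eyelid-reflection sample in
the half-open 600 ms window after tone onset exceeds `baseline mean +
thresholdK * baseline SD`, with the baseline taken over the 3 s before the
tone. `thresholdK = 4` is the one genuinely free constant of the scoring
rule and is exposed prominently; with a flat baseline (SD = 0) the rule
degenerates to "any sample above the baseline mean".

`alignTrials()` cuts one row per trial at the frame rate relative to tone
onset (first sample at or after the onset; half-open windows throughout).
Area under the curve is the rectangle rule (`sum * dt`); the quadrature
choice is immaterial to the paired test and keeps areas interpretable.
`classifyModulation()` runs a two-sided paired t-test (df = n-1) of
task-window area ([0, 2) s) against baseline-window area ([-2, 0) s) over
*correct trials only*; p < 0.05 flags the ROI task-relevant and the sign
of the mean difference labels it positive or negative. Zero-variance
differences with nonzero mean are exact (p reported as 0 with a flag).
There is no multiple-testing correction by default, matching a per-ROI
α = 0.05 criterion; a Benjamini-Hochberg option exists. Latency to peak is
the time of the first maximum of the correct-trial average within
[0, 8] s. Population percentages are rounded half away from zero to two
decimals.

One caveat the validation makes visible: on sparsely active cells the
paired differences are heavy-tailed (a handful of discrete transients per
window), and the t-test's realized false-positive rate on such traces
exceeds the nominal 5% (the type-I calibration under Gaussian-noise areas
is clean). This is a property of the method, not of the implementation.

# Spatial statistics

Centroids are converted to µm by the pixel pitch; no edge correction is
applied at the field boundary. The resampling test draws, 500 times, a
subset-sized sample *without* replacement from all ROIs (with replacement
between draws), recomputes the median pairwise distance, and compares the
observed subset median against that null. The default `tail = "upper"`
counts null medians at or above the observed value: the working
hypothesis is that positively modulated cells are *sparser* than chance,
and only upper-tail counting can call a subset with a median *above* the
null mean significant. The literal lower-tail counting is implemented and
selectable; the tail used is always reported. A p of 0 means
p < 1/nResamples (no smoothing is added). When the subset is the whole
population every draw reproduces the observed statistic and the
upper-tail p is 1 — the test cannot be spuriously significant in the
degenerate case.

Adjacency counts: for each ROI, the number of neighbors of each label
within 50 µm (self excluded), aggregated as mean ± SD by reference label.
The group comparison (positive-neighbor counts around positive cells vs
around all other cells) uses the Wilcoxon-Mann-Whitney rank-sum with
midranks, tie-corrected variance, no continuity correction, two-sided
normal p — the convention under which a printed z of 2.97 corresponds to
p = 0.003. Exhaustive enumeration at n = 8 per group shows this
approximation sits within the discreteness of the exact permutation null
(local atom + a few percent); the tests validate the implementation
exactly against an independent implementation of the same estimator and
hold it to that discreteness-limited tolerance against the permutation
oracle.

# The simulator

`makeGroundTruth()` + `renderMovie()` generate the test bed. Frames are

    quantize16( illum * bleach(t) * shift(content(t)) + noise )

where `content(t)` is a static scene (tissue background 1000 counts,
somata +150 counts resting) plus transient kernels, shifted by the
planted motion; the illumination field (radial vignette, 20% corner drop)
is static in the camera frame — deliberately, since that is exactly the
artifact the homomorphic step must remove.

Choices a reader may want to audit, each fixed before validation and kept:

* **Geometry**: 512 × 512 px desk-scale frames at the acquisition pixel
  pitch of 1.312 µm/px (so size thresholds transfer to 1024 × 1024
  sessions), 20 Hz, 2000 frames by default; 50 somata of radius 5.7 px
  (15 µm diameter) with a flat-top (supergaussian) radial profile —
  somata are filled discs, not Gaussian spots — placed by dart throwing
  with centers at least one diameter apart.
* **Kinetics**: `k(t) = (1 - e^(-t/0.045)) (e^(-t/0.4))` — GCaMP6f-like
  fast rise and sub-second decay (literature-typical; both configurable).
* **Rates and amplitude**: spontaneous transients at 0.1 events/s/cell
  (CA1-typical sparse firing); transient amplitude 600 counts, i.e. a
  peak of ~36% dF/F over the resting soma — the burst regime that
  wide-field recordings actually detect. Positively modulated cells (19%
  of cells) emit an extra transient with probability 0.9 in the 0-0.6 s
  window after the tone of a correct trial; negatively modulated cells
  (24%) are tonically active (3x base rate) with the rate suppressed to
  10% for 2 s after correct-trial tones — rate suppression is the
  mechanism, and tonic activity is what makes a suppression visible.
* **Motion**: respiratory sinusoid of 0.8 px (~1 µm) at 2.5 Hz plus rare
  (0.02/s) biphasic jumps of ~5 px lasting two frames.
* **Bleaching**: exponential from 1 to 0.933 over the session (a ~6.7%
  whole-session loss).
* **Noise**: additive read noise (SD 10 counts) plus shot noise with
  variance equal to the signal; `readNoiseSigma = 0` switches *all* noise
  off for exact closed-form checks.
* **Trials**: 40 tone-puff trials, ITI uniform in [31, 36] s, 82.5%
  planted correct (33/40); trials whose analysis windows do not fit the
  movie are dropped, so short movies carry fewer trials.

All randomness derives from one master seed through fixed per-component
sub-streams (placement, schedule, labels, events, motion, noise, eyelid,
trace noise), so changing the noise model does not move the cells.

What the simulator does **not** emulate: optical PSF and scattering,
z-axis defocus or non-rigid deformation, neuropil and out-of-focus
background dynamics, overlapping somata (placement enforces separation),
hemodynamic artifacts, and temporally correlated noise. Passing the
recovery tests therefore demonstrates that the algorithms do what they
claim on movies obeying the stated model — rigid motion, multiplicative
static illumination, additive pixel noise — not that they segment
arbitrarily dense or scattering-limited real tissue.

# Validation and problem sizes

The test suite validates each stage against independent oracles: exact
brute-force recomputation (pixel statistics, z-scores, median distances,
adjacency counts), closed forms (transient kernel time courses, bilinear
midpoints, t statistics), independent reference implementations
(`t.test`, `wilcox.test`, an unblocked reference clustering, a rescan
overlap filter), exhaustive permutation (rank-sum), and planted ground
truth (motion, cells, labels, outcomes).

Problem sizes were chosen so the full suite runs in well under half an
hour on one core: the end-to-end recovery run uses the default 512 × 512,
2000-frame, 50-cell movie, rendered to multi-page TIFF parts and streamed
through the correction (`renderMovieFiles()` + the file input of
`correctSequence()`, verified bit-identical to the in-memory path) so
that only the corrected movie is resident (~4 GB peak, 7-8 minutes); the
registration accuracy check uses 128 × 128 × 100 noise-free frames;
task-modulation recovery uses 50 cells over a full 40-trial session
simulated at the trace level (rendering frames would add nothing to a
trace-level statistic); the type-I calibration uses 1000 null ROIs. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch and writes the headline numbers as JSON.

# Known limitations

* Rigid translation only; rotation, shear and z-motion are out of scope.
* Detection keys on temporal activity: a cell that never fires is
  invisible, and a tonically active cell whose own variance inflates its
  z-denominator is penalized — both inherent to the z-score approach.
* The overlap filter resolves redundancy by deletion, not demixing;
  coincidentally overlapping cells are reported as one survivor.
* The paired t on sparse event-count differences is anticonservative
  (see above); treat per-ROI significance near the threshold with care.
* `thresholdK = 4` for eyelid scoring is a package default, not a
  community standard; calibrate it per rig.
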