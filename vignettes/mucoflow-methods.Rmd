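---
title: "Quantifying ciliary beating and mucociliary clearance with mucoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliary beating and mucociliary clearance with mucoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoflow)
```

## What this package measures

Differentiated airway epithelium — on cell-culture inserts or perfused
organ-on-chip devices — is functionally characterized by how well its motile
cilia beat and how effectively they transport the overlying mucus layer.
`mucoflow` quantifies both from routine microscopy:

* **Ciliary beat frequency (CBF)** from high-speed phase-contrast video
  (hundreds of frames per second over fields of ~166 × 166 µm),
* **Mucociliary clearance (MCC)** from fluorescence videos of 1-µm tracer
  beads riding the mucus flow (tens of frames per second over ~1.2 × 1.2 mm),
* **Tissue composition and maturation** from immunofluorescence images:
  marker-positive area fractions and the line density of planar-cell-polarity
  (VANGL1) crescents.

Every analysis stage has a synthetic counterpart with exact ground truth, so
the whole pipeline can be validated end to end without any microscope.

## Coordinate and angle conventions

Images are matrices indexed `[row, col]`, origin top-left; `x` (µm) runs
rightward along the channel axis, `y` downward. The channel inlet sits at
`-x` by default (`channel_geometry(field, inlet = "-x")`). Trajectory angles
are measured from the inlet direction in degrees, in (−180, 180]: 0° is flow
straight toward the inlet, 180° toward the outlet, ±90° toward the channel
walls. Frames are 0-based, frame *k* occurring at time *k*/frame-rate.

## Ciliary beat frequency

A beating cilium modulates the intensity of the pixels it sweeps, so the
per-pixel temporal standard deviation (`motion_map()`) lights up exactly
where cilia move. The map is segmented with Otsu's threshold
(`segment_motion()`); **beat density** is the moving-pixel fraction of the
field. Because Otsu always finds *some* split, a configurable absolute floor
(`min_motion`, default 10⁻³ intensity units) suppresses segmentation of
noise-only fields: a near-constant map yields an empty mask and a warning.

For each masked pixel the detrended, lightly smoothed intensity trace is
Fourier transformed and the dominant frequency taken as the magnitude
argmax inside a physiological band. Choices worth knowing:

* **Smoothing**: a 3-frame moving average by default (`smooth_frames`); at
  200 frames/s this attenuates only far above any ciliary frequency, and
  tests confirm the peak is unchanged on clean signals with smoothing off.
* **Band**: `f_min_hz = 2` Hz to Nyquist. The lower edge excludes DC leakage
  and slow drift; human airway CBF in culture sits well above it.
* **Resolution**: one FFT bin, frame-rate/n-frames (0.39 Hz at 200 fps and
  512 frames); recovery of synthetic frequencies is verified to within one
  bin anywhere in the band.
* **Reporting unit**: per-pixel frequencies are averaged within 8-connected
  mask regions (a region is roughly one ciliated cell) and over the mask for
  the per-movie value. Per-sample summaries (`summarize_cbf()`) average
  movies without weighting; a movie with an empty mask contributes density 0
  but is excluded from the frequency mean, which is undefined without motion.
* Pixels whose in-band peak carries a negligible share of spectral energy
  (`peak_floor`) are excluded rather than assigned a spurious frequency.

## Bead tracking

`detect_spots()` performs scale-normalized Laplacian-of-Gaussian detection
with strict local maxima and 1-D quadratic sub-pixel refinement; the default
response floor is 8 × MAD of the response, a robust noise estimate.
`link_trajectories()` joins detections of consecutive frames by mutual
nearest neighbours within `max_disp_um`. There is no gap closing and no
global assignment: at the bead dilutions used in practice (1:200), mutual
nearest neighbours are unambiguous, missed detections simply split a track,
and downstream statistics operate per trajectory, so splits are benign.
Ties break by distance then spot index, making linking fully deterministic.
Tracks shorter than `min_track_len = 5` nodes are dropped.

Sub-pixel localization noise matters downstream: a σ of ~0.1 px at 30 frames
per second adds several µm/s of *apparent* per-step speed to every recovered
track. Any classifier threshold involving speed must therefore be calibrated
on *tracked* data — movies of cell-free preparations for background,
strong-flow preparations for signal — not on noise-free coordinates.

## Background-flow rejection

Slow drift and Brownian jitter of beads not engaged by cilia would otherwise
contaminate transport statistics. Nine per-trajectory features are extracted
(`extract_features()`): mean/median/s.d. of speed, path length, Euclidean
(net) distance, directness (net/path, defined as 0 for a stationary track —
which correctly classifies it as background), mean flow angle, node count,
and maximal acceleration. The mean flow angle is the angle of the *mean
displacement vector*, not the circular mean of step angles: it needs no
wrap-around treatment and is stable for jittery tracks.

Two classifiers are provided:

* `train_tree()`: a depth-5 classification tree (minimum leaf 5) scored by
  stratified 5-fold cross-validation; the reported accuracy is always the
  held-out one.
* `calibrate_thresholds()` / `threshold_classify()`: the simplified rule —
  *background iff* Euclidean distance, median speed **and** directness all
  fall below their thresholds. Calibration grid-searches quantile triples
  (up to each feature's maximum, so a feature that does not discriminate in
  a given data set can be neutralized) maximizing balanced accuracy; ties
  resolve to the component-wise median, placing each cut mid-gap.

On the default synthetic benchmark (2,000 labelled tracks) both exceed 95%
held-out accuracy. The AND-structure of the simplified rule has one known
blind spot: optically overlapping bead pairs produce flickering tracks with
near-zero net displacement but arbitrarily large apparent speed, which no
bounded speed cut can catch; the tree, leaning on directness and net
distance, rejects them. Both are exposed; `filter_background()` applies
either and never alters surviving coordinates.

## MCC statistics

For each surviving trajectory the transport direction is the angle θᵢ of its
start-to-end line (`trajectory_angles()`; zero-displacement tracks are
excluded with a logged count but still contribute velocity observations).
The **polar order parameter** is the dot product of the mean unit vector
û = ⟨[sin θᵢ, cos θᵢ]⟩ with the inlet unit vector n̂ (`polar_order()`);
with angles measured from the inlet this reduces to ⟨cos θᵢ⟩. PO is 1 for
coherent flow toward the inlet, −1 toward the outlet, and near 0 for
isotropic or wall-directed flow — note that a PO of 0 does *not* mean no
transport, only no axial bias; the angle histogram
(`angle_histogram()`, one count per trajectory) disambiguates.

`velocity_field()` grids per-step velocities (assigned by step midpoint —
symmetric, avoiding directional bias) into cells of `grid_um` (default
20 µm, ~the trajectory scale at 1.2-mm fields) and averages u and v per cell
over all observations, since several beads may pass the same spot. Coverage
`mcc_coverage()` measures the coherent area with measurable flow: the active
cells are rasterized and morphologically closed with a disk of radius
`alpha_um` (default 2 × grid spacing), so gaps narrower than the disk are
absorbed into the coherent area while isolated cells keep their own
footprint — a concave-hull construction at characteristic radius α.
C_MCC = A_MCC/A_Total, with A_Total the full field of view. Fewer than
3 active cells yield zero area. The estimate agrees with a brute-force
active-cell count within 10% on dense random point sets. The area-averaged
speed is M̄ = C_MCC·⟨|U|⟩ — the mean active-region speed discounted by the
covered fraction — so M̄ ≤ ⟨|U|⟩ with equality only at full coverage.
`pool_sample()` concatenates angles across movies before recomputing PO
(a trajectory-level pool) and averages field metrics weighted by field area.

## Immunofluorescence quantification

`area_fraction()`: median filter → CLAHE (to flatten illumination) →
automatic threshold (Otsu default; triangle and mean exposed) → positive
fraction. Images whose post-preprocessing dynamic range falls below
`min_range` are declared degenerate (fraction 0, flagged) because automatic
thresholding of a unimodal histogram is meaningless.

`detect_crescents()`: Gaussian → median → adaptive Wiener denoising, then a
Frangi-type Hessian eigenvalue ridge response maximized over scales, Otsu
threshold, and removal of components under `min_size_px`. Scales should sit
near half the expected stroke width (default {1, 2} px for 2–4 px strokes);
scales much wider than the stroke produce a response halo that degrades the
mask. A minimum-signal guard (robust contrast below `min_contrast` × MAD →
empty mask) prevents the self-normalizing ridge response from segmenting
structure-free noise.

`crescent_density()` skeletonizes each component (Zhang–Suen thinning plus a
redundant-corner pruning pass that leaves minimal 8-connected chains) and
measures length by weighted link counting. The naive rule — 1 per orthogonal
link, √2 per diagonal — overestimates digitized lines at intermediate
orientations by up to ~8% (staircase bias), so the default applies the
classical chain-code correction (0.980/1.406 with −0.091 per direction
change), accurate to ~1% on straight lines at any orientation; the naive
rule remains available (`correction = "none"`). The density is
D_C = ΣLᵢ/A with A the field area in µm²; per-donor summaries average
fields of view without weighting.

## The synthetic-data module

The generators emulate the acquisition geometries above with known truth:

* `gen_cilia_video()`: circular patches oscillating sinusoidally at set
  frequencies on a noisy static background (defaults: 200 frames/s, ~3 px/µm,
  498 × 498 px ≈ 166 µm fields). What it does *not* emulate: metachronal
  phase gradients, waveform harmonics, or illumination drift — so passing
  tests certify frequency recovery, not waveform analysis.
* `gen_bead_tracks()` / `render_bead_video()`: directed MCC tracks (per-bead
  speed ~ Normal(20, 5) µm/s — a strong-flow regime; the paper-scale fields
  are 1.2 mm at 30 frames/s) and background tracks as Brownian motion with
  D = 0.4 µm²/s (the Stokes–Einstein value for a 1-µm bead in water at room
  temperature) plus a slow 0.5 µm/s drift. Rendering uses an isotropic
  Gaussian PSF (σ = 1.5 px) with additive Gaussian noise; Poisson photon
  statistics and bead aggregation are out of scope.
* `gen_crescent_image()` / `crescent_arcs()`: anti-aliased arc strokes with
  exact analytic lengths. Arcs subtend at most π (a crescent lines at most
  ~half a cell boundary) and are placed with ≥3 µm separation — crescents
  belong to distinct cells and do not cross; merged strokes would
  under-count length at junctions.
* `gen_marker_image()`: blob masks hitting the requested positive fraction
  exactly before noise. A requested fraction of 1 is rejected: with no
  background class, automatic thresholding is undefined.

All generators are bit-reproducible under a fixed seed, and each manifest
suffices to compute every downstream target without re-reading pixels.

## Problem sizes and the benchmark

`run_benchmark()` simulates all modalities, runs every stage, and compares
each recovered metric to truth at stated tolerances (PO and coverage ±0.05,
density and fraction ±0.02, CBF within one FFT bin, crescent density ±5%,
accuracy ≥95%). The default configuration uses a 128-px CBF field with 256
frames, 600-µm flow fields with 240 beads, and 1,000 tracks per class for
classification — sizes chosen so a full run completes in seconds on a
laptop while keeping every tolerance meaningfully tight; all sizes are
plain config entries (`default_benchmark_config()`, YAML-overridable via
`load_run_config()`). Disabling the classifier (`classifier_enabled: false`)
demonstrably inflates coverage relative to truth, and the report flags it.
Reports embed the config hash and seed; identical configs reproduce all
numbers exactly.

## Known limitations

* PO is a per-trajectory statistic; heavy track splitting biases it toward
  the behaviour of short fragments. Filter length thresholds accordingly.
* The concave coverage area is raster-based at grid resolution; alpha values
  below the grid spacing are rounded up to one cell.
* The threshold rule's AND-structure cannot reject high-apparent-speed
  artifacts (see above); prefer the tree when such artifacts are plausible.
* Skeleton-based lengths assume strokes wider than ~2 px and fields where
  crescents do not touch; touching crescents merge and under-count slightly.
* Synthetic benchmarks certify the estimators, not biology: real recordings
  add focus drift, mucus heterogeneity and optical artifacts that no test
  here exercises.
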