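---
title: "Methods: quantifying vascular remodeling, cell motility, and optical quality in longitudinal bone-marrow microendoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vascular remodeling, cell motility, and optical quality in longitudinal bone-marrow microendoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(limbquant)
```

## Scope and scientific setting

Implanted gradient-index (GRIN) microendoscopes make it possible to image
the same femoral bone-marrow volume of a living mouse for weeks to months:
the implant is rigidly fixed to the bone, so the field of view revisits
the same tissue at every session. `limbquant` implements the
quantification layer for such experiments:

* **Optical quality control** — point-spread-function (PSF) width from
  sub-resolution bead stacks, and a signal-to-noise (SNR) metric.
* **Vessel remodeling** — segmentation of the intravascular-tracer
  channel, a per-voxel local-diameter map, and a normalized
  volume-change statistic per vessel, stratified by diameter class.
* **B-lineage cell motility** — detection, volume-based classification
  into B cells and plasma cells, frame-to-frame track linking, a
  track-length inclusion filter, and per-track motility metrics.
* **Photoactivation analysis** — ROI fluorescence across sessions after
  photoactivating a GFP variant, exponential decay fitting, and a
  positional-stability report.
* **Micro-CT morphometry** — cortical thickness from a two-Gaussian
  intensity-profile fit and bone volume / bone surface (BV/BS) ratios.
* **Welfare analytics** — total clinical scores and activity
  normalization of post-surgical tracking records.

Because raw in-vivo stacks of this kind are not publicly archived, every
stage is exercised against a first-class synthetic-data module that
renders scenes with known ground truth. The synthetic scenes define the
study conditions; the tests and the acceptance script measure how well
the analysis recovers what the generator put in.

## Image container and conventions

All images live in a `time_lapse_volume()`: named channels of 4D arrays
`[x, y, z, t]` with physical voxel sizes in micrometres and per-frame
timestamps. Coordinates are physical (µm), the origin sits at the stack
corner, z runs along the optical axis, and voxel `i` of an axis has its
center at `(i - 0.5) * voxel_size`. A voxel belongs to a rendered shape
when its center lies inside it. Voxel metadata is mandatory on disk
(TIFF stacks carry a JSON sidecar); `read_stack()` refuses input without
a voxel size, because a silently assumed µm³ would corrupt every
downstream statistic.

All morphological primitives honor anisotropic spacing: the Euclidean
distance transform is computed with the exact separable
parabolic-envelope algorithm using per-axis physical spacing, and all
metric computations (linking distances, drift, diameters) are done in µm.

## The synthetic scenes

### Acquisition defaults

`scene_config()` carries the acquisition geometry of the modeled
instrument: a circular field of view of 280 µm diameter inside a
350 × 350 µm² frame at 507 × 507 pixels (0.7 µm pixel pitch), 70 µm
z-stacks at a 6 µm step, one stack every 30 s for 45 min, and a PSF of
0.8 µm FWHM laterally and 5.2 µm axially. The noise model is Poisson
shot noise on the expected photon count plus zero-mean Gaussian read
noise; the signal amplitude is scaled so that `snr_target` (default 10)
times the background standard deviation `sqrt(background + read_sd²)`
equals the amplitude. A fixed seed makes every scene byte-identical.

### Vessel-remodeling scenes

`generate_vessel_scene()` renders two sessions of a small vascular bed.
The movie geometry above is deliberately *not* reused here: remodeling
is measured on static per-session stacks, and a 6 µm z-step undersamples
5–15 µm vessels, so the default vessel scene
(`vessel_scene_config()`) uses isotropic 2 µm voxels over
200 × 200 × 80 µm³ with the FOV circle covering the full width. Five
straight tubes (capsules) of three diameter classes — small drawn from
7–13 µm, mid from 17–30 µm, large from 38–46 µm — run along y. Wide
vessels are placed in central lateral slots and the axial plane of each
tube is chosen greedily to maximize surface clearance (≥ 4 µm after
accounting for radii), so that no tube is clipped by the FOV circle and
no two tubes merge after PSF blur. The class diameter ranges keep at
least one voxel (2 µm) of margin to the 5/15/35 µm class edges because
the diameter measurement is accurate to about one voxel; sampling a
"large" vessel at 35.5 µm would make its class assignment a coin flip
and test nothing.

Remodeling is realized per vessel as two disjoint interior slabs of the
tube: one present only at session 0 (disappearance) and one present only
at session 1 (appearance). For a target normalized volume change `r`
(symmetric difference over session-1 volume), each slab must occupy the
volume fraction `f = r / (2 + r)` of the tube; the slab length in
2 µm segments is corrected for the capsule's hemispherical end caps and
rounded stochastically so that its expectation is exact. The recorded
ground truth is *re-measured from the rendered noiseless label masks*,
so voxelization is part of the truth, not an error term. The default
class rates (0.4, 0.15, 0.05 per 24 h) realize the regime in which small
vessels remodel fastest; absolute rates are free parameters of the
generator since no published per-class rates exist.

### Cell scenes

`generate_cell_scene()` renders B cells (volumes drawn from
150–450 µm³, below the 500 µm³ class boundary) as spheres moving by a
persistent random walk with constant step length `speed × Δt` and
direction correlation 0.8, reflecting at the walls; plasma cells
(600–1500 µm³) jitter inside a 3 µm confinement radius around a fixed
niche position. The default B-cell speed of 4 µm/min is a typical bone
marrow B-cell motility scale. Trajectories are always returned as ground
truth; rendering can be switched off for tracker-only studies.

### Photoactivation scenes

`generate_photoactivation_scene()` produces one pre-activation frame at
baseline and one frame per imaging session in which a central cuboid ROI
(default 75 × 75 × 30 µm³) starts at `fold_increase` (default 100)
times baseline and decays as `exp(-(turnover + emigration) t)`. The two
loss mechanisms — protein turnover and emigration of labeled motile
cells — are not separately identifiable from ROI means, which is why the
decay fit is single-exponential by default (see below).

### Micro-CT phantoms and bead stacks

`generate_ct_phantom()` builds two parallel cortical walls whose
cross-line intensity profile is exactly the sum of two Gaussians with
FWHM equal to the requested wall thicknesses, at the instrument's
isotropic 10.5 µm voxels. `generate_bead_stack()` renders point-like
beads as anisotropic Gaussians at sub-voxel positions (0.2 µm lateral /
0.8 µm axial sampling), with a minimum mutual separation enforced on an
ellipsoidal metric matched to the axially elongated PSF.

### What the generator does not emulate

No blood flow, no breathing or cardiac motion, no depth-dependent
aberrations or scattering, no autofluorescence texture, no vessel
branching or curvature, and no photobleaching. Passing tests therefore
demonstrate correctness of the measurement pipeline under the stated
noise and geometry model — not robustness to every artifact of real
intravital data.

## Vessel remodeling analysis

`segment_vessels()` smooths with an isotropic Gaussian (default FWHM
2.5 µm ≈ 1.25 voxels), applies a global Otsu threshold, removes
components below 100 µm³, and fills enclosed holes. The smoothing
default was chosen to suppress single-voxel boundary flicker caused by
independent per-session noise while still resolving the thinnest
remodeling slabs (2 µm) rendered by the generator; both requirements
were verified on noiseless and noisy scenes.

`local_diameter()` implements local thickness in the
maximal-inscribed-sphere sense: for every foreground voxel, the diameter
of the largest sphere that fits in the foreground and covers the voxel.
Candidate spheres (radius = exact Euclidean distance to the nearest
background voxel center) are taken on the distance ridge
(plateau-tolerant local maxima of the distance transform), spheres
contained in an already-accepted larger sphere (`|c1 − c2| + r1 ≤ r2`)
are discarded, and accepted spheres are painted in decreasing radius
order; every voxel keeps its own inscribed sphere as a floor value. On a
digital cylinder of radius 10 µm the median map value is 20 µm to within
one voxel. Components whose maximal inscribed radius is below one voxel
report one voxel size, with a warning.

`pair_sessions()` optionally registers the sessions by the integer-voxel
translation maximizing binary cross-correlation (FFT-based); the default
is no registration, since the implant itself provides a fixed frame of
reference. `remodeling_statistic()` then partitions the union of both
masks into 26-connected components ("vessels"), assigns each component a
class by the *median* local diameter over its session-1 voxels
(half-open bins [5, 15), [15, 35), [35, ∞) µm; components below 5 µm
are excluded), and reports per vessel

delta = (V_appear + V_disappear) / V_t1,

the symmetric-difference volume normalized by the later session's
volume. Components absent at session 1 are tallied as "fully
disappeared" and excluded from class means rather than producing a
division by zero. `compare_classes()` runs a one-way ANOVA across
classes with Bonferroni-corrected pairwise follow-ups.

Three design questions were genuinely open and resolved as follows:

* **Signed or unsigned volume change.** The figure-legend wording of the
  source experiments colors appearance and disappearance separately but
  reports a single magnitude; the unsigned symmetric difference is the
  default and a signed variant `(V_appear − V_disappear)/V_t1` is
  available via `signed = TRUE`.
* **What a "vessel" is.** Connected components of the union of both
  sessions keep partially remodeled vessels in one piece; components of
  a single session would split a vessel at every transient gap.
* **Which session's diameter.** Classification uses session 1, the same
  session as the normalization denominator.

Known estimator property: with independent per-session noise, threshold
flicker of the one-voxel boundary shell adds a positive bias to the
symmetric difference that is proportional to the surface-to-volume
ratio; at the default scene and SNR it is about +0.04 on the small class
(delta ≈ 0.4) and +0.01 on the large class (delta ≈ 0.05). The
diameter-ordering of class means is unaffected; recovery tests use a
25% relative tolerance for this reason.

## Cell motility analysis

Detection thresholds differ from the vessel module on purpose: cells
occupy well under 1% of the stack, where Otsu's two-class model breaks
down, so `detect_cells()` defaults to a robust background threshold
(median + 6 × MAD of the smoothed frame). Touching cells are split by a
seeded 3D watershed on the distance transform, with seeds at distance
maxima separated by at least 6 µm (a cell radius). Volumes are voxel
counts times voxel volume.

`classify_cell()` applies the 500 µm³ boundary — the volume of a 10 µm
diameter sphere to the nearest hundred — with ties assigned to B cells,
because plasma cells are defined as strictly larger than the boundary.

`link_tracks()` uses greedy globally-nearest-first assignment per frame
under a step bound (default 10 µm/frame ≈ 20 µm/min at 30 s, well above
B-cell speeds), with gap bridging up to one missing frame and the step
bound scaled by gap length. Ties are broken deterministically by
(distance, lower track id), which makes linking invariant to detection
input order. An exhaustive minimal-total-distance oracle
(`link_tracks_exhaustive()`) is kept for tests; at realistic densities
greedy and optimal agree.

`filter_tracks()` implements the inclusion rule of keeping only tracks
present for *strictly more than* 10 recorded time points, so every
retained track spans at least 5 min at the 30 s default interval.
`motility_metrics()` reports mean velocity (mean per-step speed) and
displacement rate (straight-line start-to-end distance over duration),
both in µm/min and in 3D physical coordinates; the triangle inequality
guarantees displacement rate ≤ mean velocity, with equality only for
monotone collinear motion. No drift correction is applied: the implant
is positionally stable, which the photoactivation module verifies
directly. Group comparisons use Welch's two-sided t-test.

## Photoactivation analysis

`quantify_roi()` reports, per session, the ROI mean intensity, the
above-threshold fluorescent volume, and the intensity-weighted centroid
of above-threshold voxels. The ROI is fixed in stack coordinates — the
implant is the frame of reference, so ROI tracking would mask exactly
the instability one wants to measure. The default detectability
threshold is twice the ROI median of the first (pre-activation) session.
`fit_decay()` fits `I(t) = A exp(-k t) + C` by Levenberg–Marquardt
least squares with log-linear initialization, recovers exactly on
noiseless exponential input, reports `rate ≤ 0` with a warning on
non-decreasing series, and short-circuits constant series to rate 0.
`stability()` reports per-session centroid drift relative to the first
session with defined signal, and the persistence horizon — the last
session time with any above-threshold ROI volume.

## Micro-CT morphometry

`profile_thickness()` samples the intensity along a user-placed line by
trilinear interpolation and fits a sum of two Gaussians plus a constant
baseline. The reported wall thickness is the FWHM (`2√(2 ln 2) σ`) of
each Gaussian; σ itself is also returned, since the thickness-from-width
convention is not standardized. Initialization takes the two strongest
profile peaks separated by at least a tenth of the line; fewer than two
peaks, a fitted center outside the line, or a center separation below
half the summed widths raise a "walls unresolved" error. The fit is
translation-invariant along the line, and measuring contralateral bones
at mirrored positions is supported by `mirror_stack()`.

`bone_morphometry()` requires isotropic voxels, binarizes at a fixed or
Otsu threshold, and reports BV (voxel count × voxel volume), BS
(exposed voxel faces × face area, grid-boundary faces counted), and
BV/BS in mm units. Face counting was chosen over mesh extraction
because it is exactly testable (a 10³ cube has 600 faces) and fully
adequate for ratio comparisons at 10.5 µm voxels; it overestimates
absolute curved surfaces by up to ~1.5× (the digital-surface metric
property), which cancels in paired BV/BS comparisons against a
like-measured contralateral bone. Paired designs use the paired
two-sided t-test.

## Welfare analytics

`total_score()` sums exactly eight clinical subscores, each on a 0–3
scale (total 0–24). The factor list in the source protocol names seven
items for "eight factors"; the schema therefore enforces eight generic
factor columns and treats names as labels, rather than guessing the
eighth factor's identity. `normalize_activity()` divides each day's
sensor-crossing count by the subject's mean over the three days
immediately pre-surgery, making the pre-surgical mean exactly 1 by
construction; a missing pre-surgery window or a zero baseline is an
error, not a silent NA.

## Numerical choices and degenerate inputs

* Distance transforms: exact squared-distance envelope algorithm,
  per-axis physical spacing; foreground with no in-grid background maps
  to half the grid extent.
* Otsu threshold: 256-bin histogram between-class variance; constant
  images return the constant (segmentation then warns and returns an
  empty mask).
* Bead fits reject on: non-convergence, residual RMS > 20% of
  amplitude, centroid shift > 1 voxel from the seed, or FWHM at the
  window boundary; PSF summaries use the sample (n−1) standard
  deviation and warn when n = 1.
* All statistical helpers handle degenerate variance explicitly
  (identical groups give p = 1, not NaN).
* One global seed fans out to per-stage seeds via a deterministic hash
  (`derive_seed()`), all below 2³¹, so any stage can be rerun
  independently yet reproducibly.

## Problem sizes used by the test-suite

The shipped tests run the full vessel pipeline on 20 seeded scenes of
100 × 100 × 40 voxels, bead stacks of 130 × 130 × 62 voxels with 23
beads (plus 5 × 23 noisy beads for the bias Monte-Carlo), 1000-replicate
null simulations for both statistical helpers, and 60–120 replicate
power/bias simulations elsewhere. These sizes were chosen so the whole
suite completes in a few minutes on one CPU while keeping every
statistical check adequately powered.

## Known limitations

* The remodeling statistic inherits the positive boundary-flicker bias
  described above; on real data with correlated session noise the bias
  structure may differ.
* Diameter accuracy is one voxel; vessels near a class edge can change
  class between sessions.
* The PSF model is a separable anisotropic Gaussian; no aberration or
  depth dependence is modeled or fitted.
* The tracker handles neither cell division nor merging, and the
  volume-threshold classifier knows only two classes.
* Micro-CT analysis covers cortical thickness and BV/BS only; no
  trabecular morphometry (Tb.Th, Tb.Sp) is attempted.
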