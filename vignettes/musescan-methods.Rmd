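---
title: "Scan planning, calibration, fusion and margin classification: methods"
author: "musescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan planning, calibration, fusion and margin classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musescan)
```

# The problem

Intraoperative tumor-margin assessment asks whether the resection surface
of a freshly excised specimen still carries cancer cells. Slide-free
microscopy with ultraviolet surface excitation (MUSE) images the stained
superficial cell layer directly, without sectioning, but an excised
specimen is an irregular 3D object: a single camera pose cannot keep a
curved, centimetre-scale surface in focus. The computational chain this
package implements drives a robotic microscope over a triangulated
surface mesh of the specimen and turns the captured image clusters into
a classified margin map:

1. **geometry** — mesh ingestion and cleaning, surface centroid and
   local-normal estimation, and surface reconstruction from oriented
   points;
2. **trajectory** — decomposition of the mesh into FOV-sized grids, a
   Z-X-Y Euler pose and a focus-elevation schedule per grid, and a
   rotation-minimizing visiting order;
3. **calibration** — the homography projection model `H = A·B` and the
   fits that calibrate magnification, extrinsics, rotation-stage offsets
   and linear-stage skew;
4. **fusion** — Laplacian-pyramid extended depth of field per grid and
   per-tile histogram equalization;
5. **synthesis** — projection of tiles onto facets, Markov-random-field
   view selection, Poisson seam blending, intensity inversion and
   pseudo-H&E rendering support;
6. **cad** — 128-pixel subimaging, k-means nucleus segmentation, four
   nuclear features, a logistic margin model and ROC evaluation;
7. **synthetic** — generators that emulate every instrument input so the
   whole chain runs and is tested offline.

# Conventions and the projection model

Geometry is in millimetres, right-handed, origin at the calibration
chessboard center, z up. The projection model works in micrometres. The
microscope is modeled as an infinity-corrected system: the intrinsic
matrix is `A = diag(m/du, m/du, 1)` in pixels per um, with magnification
`m` and sensor pixel pitch `du = 4.5` um; the extrinsic matrix `B`
carries the top two rows of a rotation plus a translation in um. Because
the chessboard plane is z = 0, `B` acts as the 3-by-3 affine matrix
`[[r11, r12, tx], [r21, r22, ty], [0, 0, 1]]` and the homography
`H = A·B` maps board-plane um to pixel offsets from the image center at
`(pixel_N/2, pixel_N/2)` (no half-pixel shift). The FOV edge is
`l = du · pixel_N / m`: 4.608, 2.304 and 1.152 mm for the 5x, 10x and
20x presets (the instrument prints these truncated to 4.60 / 2.30 /
1.15).

```{r}
compute_fov(objective_preset("5x"))
```

# Trajectory planning

Planning starts at the area-weighted surface centroid. The raw centroid
of a curved mesh lies off-surface, so it is snapped by projecting onto
the tangent plane at the nearest vertex. We chose this first-order
projection over a nearest-facet snap deliberately: on a symmetric
tessellation (a hemisphere, say) the nearest-facet rule has many exactly
tied chordal facets and lands arbitrarily on one of them, while the
tangent-plane rule respects the symmetry and returns the apex.

From each accepted grid center, the local tangent plane is a
least-squares fit to the k = 12 nearest vertices (a k-d-tree style
neighborhood query), oriented by the mean vertex normal. Four tangent
step directions are the coordinate axes projected onto that plane; when
the normal is parallel to an axis the whole set degrades to an
orthonormal tangent pair derived deterministically from the axis of
smallest normal component. Candidate neighbor centers sit
`overlap_factor · l` away (default 0.8, giving roughly 20 percent FOV
overlap for registration); off-surface candidates snap to the nearest
surface point, candidates closer than `0.5 · overlap_factor · l` to an
existing center merge with it, and a candidate that contributes no new
member vertices is discarded — that is the mesh-boundary termination
rule. Distances in the merge rule are chordal (Euclidean): at grid scale
the chordal and geodesic metrics differ negligibly on tissue-like
curvature, and the chordal rule is exact on flat specimens where the
spacing contract (`0.8 l` exactly) matters most. A final sweep seeds
extra grids at any vertex left uncovered, so membership is a guarantee,
not a hope.

Per grid, the pose solves the Z-X-Y Euler angles whose rotation-matrix
third column equals the averaged member normal, in closed form
(`ry = atan2(nx, sqrt(ny^2 + nz^2))`, `rx = atan2(-ny, nz)`); tilts
beyond the 83.3-degree stage limit raise an error rather than silently
clamping. The elevation schedule covers the member elevation range
padded by 0.2 mm on both sides, at steps no larger than the objective
depth of field, with the frame count clamped to the instrument's 10-30
range by even re-spacing. The preset `dof` values (0.05 / 0.02 / 0.008
mm for 5x / 10x / 20x) are effective axial steps chosen so that typical
grid elevation ranges land inside that 10-30 frame window.

The visiting order is a greedy nearest-neighbor tour from the centroid
grid under cost `|drx| + |dry| + 0.01 · ||dxyz||` (degrees; the small
Euclidean term breaks ties). Greedy tours are not optimal in general, so
the implementation falls back to the input order in the rare case the
greedy tour costs more — the contract "never worse than the input
order" holds unconditionally, and tests benchmark the tour against the
exhaustive optimum for up to 8 grids. The R_z stage is set per pose to
the multiple of 90 degrees that maps the target into quadrant I; rz does
not participate in the tour cost, since sample rotation is a per-
quadrant, not per-grid, operation.

# Calibration fits

*Magnification.* The board-to-pixel map under an in-plane pose is an
exact 2D similarity with scale `m/du`, so the joint least-squares
problem over (m, in-plane rotation, translation) has the closed-form
similarity solution, which is the maximum-likelihood optimum under
isotropic pixel noise; no iterative polish can improve it. Recovery is
at machine precision noise-free and well under 0.01 at 0.1 px noise.

*Extrinsics.* Given `A`, the six affine parameters of `B` solve by
linear least squares; `r13`/`r23` complete the rows to a valid rotation,
and the out-of-plane tilt is read from the singular values of the 2-by-2
block (`cos(tilt) = sigma_min/sigma_max`). The parallelism metric is the
maximum deviation of those singular values from 1.

*Rotation-stage offsets.* The positional correction solves
`(offset_x, offset_y, 1)^T = H^-1 (O_x − pixel_N/2, O_y − pixel_N/2,
1)^T` with the third component renormalized; between calibrated step
angles corrections interpolate piecewise-linearly, and queries outside
the calibrated range are refused rather than extrapolated.

*R_z axis and stage skew.* The imaged chessboard-center positions under
incremental rotation are fitted with the algebraic (Kasa) circle fit —
closed-form, deterministic, and adequate at micrometre noise scales,
where the iterative geometric fit differs negligibly. Stage skew is a
total-least-squares line through the recorded square vertices, reported
as the signed angle to the nominal axis.

# Fusion and equalization

Each frame of a focal stack is decomposed into a Laplacian pyramid
(depth 5, 5-tap binomial kernel `[1,4,6,4,1]/16`, reflected borders).
At every band-pass level each coefficient is taken from the frame with
the largest absolute response — ties break toward the lower frame index
for determinism — and the low-pass top level is averaged across frames.
The merged pyramid reconstructs exactly, so a stack of identical frames
returns the frame to floating-point precision. Because coefficients
from different frames can mix at focus boundaries, reconstruction can
ring slightly past the input range; the output is clipped to the frame
envelope. On synthetic defocus stacks the fused tile retains more than
98 percent of the all-sharp reference's Tenengrad score.

Histogram equalization (256 bins, full 0-255 range) is applied per tile
after fusion, in that order; constant tiles pass through unchanged, and
re-equalizing an equalized tile moves pixels by less than two intensity
units.

# Synthesis

A tile's camera frame is anchored at its grid center with axes from the
pose's Euler matrix; surface points project orthogonally onto the sensor
plane and through `H` to pixels. This paraxial model is exact for flat
specimens and first-order accurate on curved ones. View selection
minimizes `sum unary + lambda · sum [neighbor labels differ]` with
`unary = 1 − cos(facet normal, view axis)`, solved by iterated
conditional modes from the best-unary initialization with ordered facet
sweeps — deterministic, provably non-increasing in energy, exact at
`lambda = 0`, and within 5 percent of the exhaustive optimum on the
small graphs where enumeration is feasible. Brightness seams are removed
by per-patch Poisson editing: interior gradients come from the source
patch, seam boundary values are averaged across the two sides, other
boundary pixels keep their source values, and the sparse system is
solved directly to a 1e-6 residual.

The virtual-staining network itself is out of scope; the package
implements the reusable pieces: intensity inversion (nuclei darker than
cytoplasm, matching conventional histology contrast), the color moment
loss `L = MSE(mean_a, mean_b) + MSE(std_a, std_b)` (averaged over
channels by default; a `reduce = "sum"` switch preserves the summed
variant, since either reading of the formula is defensible), and a
deterministic Beer-Lambert pseudo-H&E mapping with fixed hematoxylin and
eosin absorption vectors, labeled synthetic — it is a rendering aid,
not a learned stain transfer.

# Margin CAD

Tiles are cut into non-overlapping 128-pixel subimages from the top
left; partial edge tiles are discarded rather than padded. At 5x a
subimage spans 115.2 um, about 0.12 mm. Only subimages within 0.5 mm of
the sectioning line keep their histology-derived labels (tangent-plane
Euclidean distance). Nuclei are segmented by 2-cluster k-means on raw
intensities with deterministic quantile (25th/75th percentile) initial
centers — a 1D two-cluster problem where Lloyd iteration from those
centers reaches the same optimum as multi-restart randomized seeding,
without touching the global RNG — and the brighter cluster is nuclei
(fluorescence convention, before inversion). Connected components are
8-connected, implemented in-package by vectorized minimum-label
propagation. The four features are the nucleocytoplasmic ratio, mean
nuclear signal intensity over the mask, and the mean and standard
deviation of component areas; an empty mask yields the zero vector
flagged excluded, as do subimages overlapping an artifact annotation
mask (scratches, hemorrhagic necrosis) by more than 10 percent.

The margin model is logistic regression on standardized features, fit
by iteratively reweighted least squares with an L2 ridge of 1e-6 as a
numerical guard, converged at a log-likelihood change below 1e-8, and
cross-checked against `glm()` in the tests. Splits are stratified 6:4
by seeded shuffle. The operating threshold maximizes Youden's J on the
training ROC; because every threshold inside the interval down to the
next observed score yields the same training confusion, the threshold is
placed at that interval's midpoint, which generalizes better than the
boundary score when classes separate widely. Evaluation reports the
full ROC (trapezoid AUC, verified against the brute-force Mann-Whitney
probability and `pROC`), sensitivity and specificity at the model
threshold with Wilson 95 percent intervals, per-feature ROCs (each
feature oriented so its AUC is at least 0.5, as a fitted univariate
model would), and 8-connected positive-margin component areas in mm².

# Surface reconstruction

No Poisson-reconstruction library is part of this package's dependency
set, so reconstruction from oriented points is implemented directly in
the same algorithm family: the classic oriented-point implicit function
(signed distance to the tangent plane of the nearest sample) contoured
at zero by marching tetrahedra on a regular grid (default 48 cells per
axis, six tetrahedra per cell, linear edge interpolation, coincident
vertices welded). Planar point sets — detected by principal-component
analysis — fall back to a hand-written incremental Bowyer-Watson 2D
Delaunay triangulation, which preserves the input points exactly. A 500-
point sphere sample reconstructs with mean point-to-surface distance
under 0.05 mm; inputs farther than 0.1 mm from the result trigger a
warning.

# The synthetic generators

All generators are pure functions of (parameters, seed): they save and
restore the caller's RNG state, and repeated calls are bit-identical.

*Surfaces* are specimen-scale (default 15 x 15 mm, height variation
bounded by 10 mm): plane, hemisphere, half-ellipsoid, or a plane plus a
seeded sum of six random-phase sinusoids rescaled to a requested
amplitude ("bumpy").

*Tissue textures* place nuclei by dart-throwing Poisson-disk sampling
with a Poisson-distributed target count. Defaults: negative tissue 1500
nuclei/mm², radius 3.5 ± 0.5 um, nuclear/cytoplasm intensities 180/60,
noise SD 10; positive tissue 3000 nuclei/mm², radius 4.5 um, nuclear
intensity 200, with the minimum spacing relaxed from one radius to 0.3
radii to emulate disorganized nuclear arrangement. These values give
nucleocytoplasmic ratios near 0.06 (negative) and 0.17-0.19 (positive)
— a contrast of well over two pooled standard deviations, the regime
the classifier guarantees are stated for. Defocus is an isotropic
Gaussian whose sigma grows at 20 px per mm of defocus distance; the
true optical point-spread function is out of scope.

*What the generators do not emulate*: optical aberrations and field-
dependent blur, stain diffusion and photobleaching, real nuclear shape
variation and clustering, tissue autofluorescence, stage vibration, and
mesh holes from occlusion. Passing tests therefore demonstrate the
correctness and internal consistency of the computational chain under
its stated model, not instrument-level performance on real tissue;
the headline diagnostic numbers on real specimens are not reproducible
without the (undeposited) image data.

# Problem sizes and numerical choices

The demo pipeline (`run_pipeline()`) plans a 15 mm bumpy surface at
mesh resolution 40, simulating each tile as a 256-pixel native-
resolution central crop of the FOV (pitch 0.9 um at 5x) so that nuclei
stay resolvable without simulating 5120-pixel sensors; as a result the
texture atlas covers the grid-center neighborhoods, and full-surface
texturing is exercised separately with full-FOV downsampled tiles in
the geometric-consistency tests (normalized cross-correlation at least
0.95 against the painted ground truth on flat and hemispherical
fixtures). Default runs produce about 27 grids and 108 labeled
subimages and finish in roughly a minute on one CPU. Acceptance-scale
checks use 1000 random homographies for the offset round trip, 20
seeded noise replicates for the estimator recoveries, 10-density sweeps
for the feature-monotonicity check, and n = 5000 for logistic
coefficient recovery.

Tie-breaks are deterministic throughout (lower frame index in fusion,
first-candidate in view selection, ordered sweeps in ICM); degenerate
inputs error early with specific messages (zero facets, collinear
neighborhoods, singular homographies, single-class training sets); and
the only global-RNG consumers are the explicitly seeded generators.

# Known limitations

- The tile projection is paraxial (orthographic onto the tangent
  plane); strong perspective at high tilt is not modeled.
- The implicit reconstruction assumes locally consistent normals;
  heavily undersampled or self-occluding surfaces can contour poorly.
- The lens model is distortion-free, as in the instrument's own
  calibration model.
- ICM is a local optimizer; the 5 percent optimality bound is verified
  only at enumeration scale.
- Greedy path ordering approximates the rotation-minimizing tour; only
  the input-order bound is guaranteed.
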