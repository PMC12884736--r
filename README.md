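# musescan

Computational pipeline for robotic slide-free 3D surface microscopy of
excised tissue — scan planning over triangulated specimen meshes,
homography-based system calibration, extended-depth-of-field focal-stack
fusion, tile-to-surface texture synthesis, and computer-aided tumor
margin classification.

## Who it is for

Researchers building or modeling MUSE-style instruments (microscopy with
ultraviolet surface excitation): a deep-UV source excites surface-bound
fluorescent stains so only the superficial cell layer emits, which makes
slide-free histology of intact specimens possible — but an excised
specimen is an irregular 3D object, so a microscope must be *driven*
over its surface and the captured image clusters must be reassembled and
classified. This package implements that computational chain end to end
and ships synthetic generators for every input (surfaces, fluorescence
textures with ground-truth nucleus masks, defocus stacks, calibration
scenes), so the whole pipeline runs and is tested with no instrument.

## The models at the core

**Projection.** The microscope is an infinity-corrected system: intrinsic
matrix `A = diag(m/du, m/du, 1)` (pixels per µm; `m` magnification, `du`
= 4.5 µm pixel pitch), extrinsic matrix `B` holding the top two rotation
rows and a translation, and homography `H = A·B` mapping chessboard-plane
µm to pixels measured from the image center. The FOV edge is
`l = du·pixel_N/m`: 4.608 / 2.304 / 1.152 mm at 5×/10×/20× (printed
4.60 / 2.30 / 1.15). After a commanded rotation the stage correction is
`(offset_x, offset_y, 1)ᵀ = H⁻¹ (O_x − pixel_N/2, O_y − pixel_N/2, 1)ᵀ`.

**Planning.** Grids propagate breadth-first from the surface centroid at
spacing `0.8·l` along tangent directions; each grid gets the Z-X-Y Euler
pose whose rotation-matrix third column is the grid's averaged normal
(tilt ≤ 83.3°), and a focus schedule covering its elevation range ±0.2 mm
at depth-of-field steps, clamped to 10–30 frames. Grid order minimizes
rotation-stage motion greedily.

**Fusion.** Per-grid focal stacks are merged by Laplacian-pyramid
maximum-absolute-coefficient selection into one all-in-focus tile,
followed by per-tile histogram equalization.

**Margin CAD.** Tiles are cut into 128 px subimages (≈0.12 mm at 5×);
nuclei are segmented by 2-cluster k-means on intensity; four features
(nucleocytoplasmic ratio, mean nuclear intensity, mean and SD of nuclear
cross-section areas) feed a logistic model fit by IRLS on a stratified
6:4 split, evaluated by ROC/AUC with Wilson confidence intervals.

## Worked example

```r
library(musescan)

mesh <- make_surface("bumpy", extent = 15, amplitude = 1.5, n = 40, seed = 1)
mesh
#> surface_mesh: 1600 vertices, 3042 facets
#>   extent (mm): x [-7.500, 7.500]  y [-7.500, 7.500]  z [-1.449, 1.500]

obj <- objective_preset("5x")
compute_fov(obj)
#> [1] 4.608

traj <- plan_trajectory(mesh, obj, compute_fov(obj))
traj
#> trajectory: 27 grids, rotation cost 99.970
traj$entries[[1]]$pose
#> microscope_pose: xyz (1.800, 2.073, 33.668) mm, r (-3.63, 3.29, 0.00) deg, tilt 4.90 deg
```

The 15×15 mm surface decomposes into 27 FOV-sized grids; the first grid
needs a 4.9° tilt and (printed separately) a 30-frame focus schedule
spanning its 1.6 mm elevation range. Calibration on a simulated
chessboard scene with 0.1 px noise:

```r
scene <- make_calibration_scene(true_m = 5, noise_px = 0.1, seed = 2)
fit <- estimate_magnification(scene$pixels, scene$board_mm)
c(m = fit$m, residual_px = fit$residual_rms_px)
#>           m residual_px
#>   5.0000044   0.1198803
```

The recovered magnification is within 5e-6 of truth and the residual
matches the injected noise level. The full synthetic pipeline — plan,
simulate and fuse focal stacks, synthesize the textured surface, extract
features, train and evaluate the margin model:

```r
res <- run_pipeline(run_config(seed = 1))
#> [plan] 27 grids, rotation cost 99.97
#> [fuse] 27 tiles fused
#> [features] 108 subimages
#> [evaluate] AUC 0.989, sens 86.4%, spec 100.0%
res$evaluation
#> eval_report: AUC 0.989 | sens 86.4% (66.7-95.3) | spec 100.0% (84.5-100.0)
```

An AUC of 0.99 on the held-out 40 % split means the four nuclear
features almost perfectly rank positive-margin subimages above negative
ones under the generator's class contrast; sensitivity/specificity are
read at the Youden-optimal training threshold.

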