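Package: musescan
Title: Scan Planning, Calibration, Focal-Stack Fusion and Margin
    Classification for Slide-Free 3D Surface Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for robotic slide-free microscopy of
    irregular tissue surfaces (MUSE-style ultraviolet surface excitation).
    Plans microscope scan trajectories over triangulated 3D tissue meshes
    (grid decomposition, Z-X-Y Euler poses, elevation schedules, rotation-
    minimizing path ordering), models and fits the homography-based camera
    calibration (intrinsic/extrinsic matrices, rotation-stage offsets,
    stage-axis skew, rotation-axis circle fit), fuses focal stacks into
    extended-depth-of-field tiles via Laplacian pyramids, maps tiles onto
    the surface with Markov-random-field view selection and Poisson seam
    blending, and classifies tumor margins from nuclear image features
    (k-means nucleus segmentation, nucleocytoplasmic-ratio features,
    logistic regression, ROC analysis). Includes synthetic generators for
    tissue surfaces, fluorescence textures, focal stacks and calibration
    scenes so the full pipeline runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
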