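Package: polyrigid
Title: Deformable 2D/3D Registration with Polyrigid Fields and
    Differentiable X-Ray Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns a preoperative 3D attenuation volume to a small set of
    intraoperative 2D X-ray projections by jointly optimizing one rigid
    transform per skeletal structure and fusing them into a smooth,
    invertible, locally rigid deformation field in the log-Euclidean
    framework. Projections are simulated as digitally reconstructed
    radiographs (Beer-Lambert line integrals with trilinear interpolating
    quadrature) and poses are recovered by gradient-based maximization of a
    multiscale patchwise normalized cross-correlation through an adjoint of
    the renderer. Includes closed-form SE(3) exponential/logarithm maps,
    mass-based and reciprocal-distance weight fields, anchor-based camera
    pose estimation, a dense per-voxel translation-field comparator,
    deformation-quality metrics (Dice, HD95, fold percentage, log-Jacobian
    spread), and a synthetic phantom generator for sparse-view and
    limited-angle study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'polyrigid-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'se3.R'
    'volume.R'
    'camera.R'
    'render.R'
    'weights.R'
    'field.R'
    'similarity.R'
    'optim.R'
    'registration.R'
    'dense.R'
    'metrics.R'
    'phantom.R'
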