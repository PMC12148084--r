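# polyrigid

Deformable 2D/3D registration of a preoperative CT volume to a small set of
intraoperative X-ray projections, for image-guided surgery and radiotherapy
workflows where only two or three views from a narrow angular range are
available.

## The model

Recovering a dense 3D deformation from a couple of projections is severely
under-determined, so this package constrains the deformation with an
anatomical prior: bones are rigid. Each segmented rigid structure
`S_k, k = 1..K` carries one rigid transform `T_k ∈ SE(3)`, and the dense
field is their convex fusion in the Lie algebra (the log-Euclidean
polyrigid framework):

    Φ(x) = exp( Σ_k w_k(x) log T_k / Σ_k w_k(x) ) · x̃

with hyperparameter-free, mass-based weights

    w_k(x) = m_k / (1 + d_k²(x)),

where `d_k` is the Euclidean distance to structure k (mm) and `m_k` its
normalized mass (volume at constant density). An alternative
reciprocal-distance weighting `w_k = 1/(1 + ε d_k²)` is provided for
comparison. The whole deformation has 6K parameters.

Projections are simulated as digitally reconstructed radiographs: negative
log-intensities are Beer–Lambert line integrals of the linear attenuation
volume, discretized by interpolating (trilinear) quadrature. The K twists
are estimated jointly by maximizing a multiscale patchwise normalized
cross-correlation between observed and rendered images with Adam
(step sizes 1e-2 rad / 1e0 mm on the rotational/translational twist
components), with gradients propagated through a hand-derived adjoint of
the renderer. Per-view camera extrinsics can first be estimated by rigid
registration (`registerCamera`); a per-voxel dense translation field
(`registerDense`) is included as the classic under-constrained comparator.

A synthetic phantom generator (`generatePhantom` / `generateCase`) produces
soft-tissue + multi-bone volumes, ground-truth motions, orbit cameras and
rendered fixture X-rays, so the whole method is testable without external
data. Metrics include Dice, 95th-percentile Hausdorff distance, the
percentage of folded voxels (non-positive Jacobian determinant) and the
spread of the log Jacobian.

## Worked example

```r
library(polyrigid)

# a 64-cube two-bone phantom imaged by two views 30 degrees apart,
# per-bone motion sampled within 10 degrees / 10 mm
case <- generateCase(phantomConfig(), maxRotDeg = 10, maxTransMm = 10,
                     nViews = 2, angularSpanDeg = 30, seed = 3)

res <- registerPolyrigid(case@volume, case@labelmap,
                         images = case@images, cameras = case@cameras,
                         renderCfg = case@renderConfig)

round(res$twists, 4)            # estimated (rot, trans) twist per bone
#>      [,1]    [,2]   [,3]    [,4]    [,5]   [,6]
#> 1 -0.0202 -0.0061 0.0055 -4.7281  2.9463 0.1543
#> 2  0.0213 -0.0232 0.0245 -7.4181 -4.4038 2.9090

round(case@gtTwists, 4)         # ground truth the generator sampled
#>         [,1]    [,2]   [,3]    [,4]    [,5]   [,6]
#> [1,] -0.0202 -0.0061 0.0054 -4.7282  2.9452 0.1546
#> [2,]  0.0214 -0.0233 0.0242 -7.4192 -4.3987 2.9078

warpedMaskDice(case@labelmap, res$field, case@gtField)
#>         1         2
#> 1.0000000 0.9990186

jacobianStats(res$field)$percentFolds   # the estimated field never folds
#> [1] 0
```

The recovered twists match the sampled ground truth to a few 1e-3 in every
component (fractions of a degree and of a millimetre); the Dice of the
warped ground-truth masks is essentially 1 and the estimated field is
topologically clean. `writeField`, `writeCase` and the
thin command-line wrapper in `exec/polyrigid` (subcommands `phantom`,
`register-camera`, `register`, `evaluate`) expose the same pipeline on
NIfTI/TIFF/JSON files.

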