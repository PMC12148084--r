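---
title: "Locally rigid 2D/3D registration: model, implementation and design choices"
author: "polyrigid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally rigid 2D/3D registration: model, implementation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrigid)
```

## The problem

A preoperative CT volume `V` gives precise 3D anatomy, but during an
intervention only a handful of 2D X-rays `I_1, ..., I_N` can be acquired,
often from a narrow angular range. Between the two acquisitions the patient
has moved non-rigidly: individual bones have rotated and translated relative
to one another, and the soft tissue has followed. Recovering the dense 3D
deformation `Phi` that aligns `V` with the intraoperative scene from two or
three projections is severely under-determined: a free-form deformation
model has orders of magnitude more unknowns than the images constrain.

This package implements a locally rigid (polyrigid) solution. The
biological prior is simple: bones do not bend. Each of K segmented rigid
structures `S_k` carries one rigid transform `T_k` in SE(3), and the dense
field is their weighted fusion in the Lie algebra,

    Phi(x) = exp( sum_k w_k(x) log T_k / sum_k w_k(x) ) x ,

so the whole deformation has 6K parameters instead of three per voxel. The
fused field is smooth, locally rigid near each bone, and in the motion
regimes of interest orientation-preserving, with no regularization terms or
their hyperparameters.

## Forward model: differentiable radiographs

Each view is a pinhole camera `K [R|t]` with the X-ray source at
`S = -R't`. A detector pixel `p` back-projects to a point `P` on the
detector plane at focal distance `f`, and the negative log-intensity along
the ray is the Beer-Lambert line integral of the linear attenuation
coefficients (LAC, 1/mm), discretized by interpolating quadrature:

    I(p) ~ ||P - S|| * sum_m V[ S + lambda_m (P - S) ] (lambda_{m+1} - lambda_m)

with trilinear sampling `V[.]` on the voxel grid. Conventions used
throughout: world units are millimetres, voxel indices are 0-based, a
voxel's world position is its centre, values outside the grid are 0 (air),
and rendered images stay in negative log-intensity (line-integral) space,
which keeps them linear in the volume.

Rays are clipped to the support box of the zero-padded interpolant by
default, so the quadrature budget is spent where the volume is non-zero.
The default step length is half the minimum voxel spacing (a Nyquist-style
choice for trilinear fields); on the smooth synthetic phantoms below the
studies use one-voxel steps, which is already in the converged regime there
(halving the step changes a homogeneous-cube chord by well under 0.5%).

## Weight fields

The influence of structure k at point x comes from its exact Euclidean
distance map `d_k(x)` (computed by a separable lower-envelope distance
transform honouring anisotropic spacing, exactly zero on the structure):

* mass mode (default, hyperparameter-free): `w_k = m_k / (1 + d_k^2)` with
  `m_k` the normalized structure mass (voxel count x voxel volume, constant
  bone density);
* reciprocal-distance mode: `w_k = 1 / (1 + eps d_k^2)`, `0 < eps <= 1`,
  the formulation used by earlier polyrigid work, which needs a decay rate
  per anatomy.

Rows of the discrete weight matrix `W` (voxels x K) are normalized to sum
to one; the weights are computed once on the moving volume's lattice and
held fixed during optimization. Off-lattice queries interpolate the
normalized weights trilinearly with border replication (interpolated rows
still sum to one), rather than recomputing distance transforms at arbitrary
points; weights are never clipped at large distances. The mass ratio is
what lets very unequal bones coexist: a small bone's influence decays into
the soft tissue in proportion to its mass, rather than competing equally
with a bone eight times its volume.

## Optimization

Both stages maximize the same similarity: the mean over scales (full and
half resolution) and channels of patchwise zero-normalized
cross-correlation with 13-pixel patches. Channels are the raw intensities
plus *signed* Sobel-x and Sobel-y derivatives; signed derivatives (rather
than the gradient magnitude) keep the similarity odd under contrast
inversion, so anti-correlated images score -1. The outer one-pixel ring of
the Sobel images is discarded (zero padding would otherwise manufacture
edges that break the affine-intensity invariance), and flat patches are
excluded from the patch mean instead of contributing 0/0.

The optimizer is Adam with step sizes 1e-2 (radians) on rotational and 1e0
(mm) on translational twist components, a 300-iteration default budget,
best-iterate tracking (the returned parameters never score below the
initial ones, which also makes the ascent property hold exactly), and
plateau-triggered learning-rate decay for fine convergence. All runs are
deterministic given their inputs and the seed.

Gradients flow through a hand-derived adjoint chain rather than an autodiff
framework: the patchwise-NCC gradient with respect to the rendered image is
computed in closed form with box filters; the renderer adjoint splats pixel
gradients back onto the voxel grid through the same quadrature and
trilinear weights as the forward pass; the spatial gradient of the
trilinear interpolant carries it to the warped sample positions; and the
differential of the exponential map on the per-voxel mixed twist is
evaluated by small central/forward differences (the map itself is smooth,
so this inner step is accurate to ~1e-10). The composite gradient is
verified against finite differences of the full objective in the test
suite (worst component agrees to ~0.3%, dominated by trilinear kinks). The
6-dof camera stage simply uses central finite differences of the objective.

### Camera stage

Per view, a rigid se(3) perturbation of the initial extrinsic matrix is
optimized, composed on the world side (`T = T0 exp(delta)`) so rotations
act near the isocentre; composing on the camera side rotates about the
source and throws the anatomy off a desk-scale detector within a few
degrees. By default the *full* volume is rendered, not only the anchor
structure: patchwise ZNCC is contrast-invariant, and the projection of a
single smooth structure under a depth translation is close to a pure
magnification change, so anchor-only rendering leaves the depth axis nearly
unobservable at this scale (we measured Adam and L-BFGS both stalling
several millimetres deep in that null valley). The surrounding anatomy's
parallax restores depth observability; anchor masking remains available for
cases where the rest of the anatomy has moved grossly. A related
sensitivity worth knowing: at a 500 mm source-to-isocentre distance, a 0.5
degree per-view extrinsic error already displaces rays by ~4 mm at the
isocentre, so downstream recovery quality degrades measurably with per-view
camera inconsistency; the pipeline test compares the composed stages
against exactly that comparator.

### Deformable stage

All K twists are optimized jointly from identity initialization.
Structures excluded from the optimization receive zero twists and are
excluded from the weight field. The vectorized forward model evaluates
`exp(W That) X` for all voxels with a closed-form Rodrigues kernel and is
tested to 1e-8 mm against a naive per-voxel evaluation and a truncated
power-series exponential.

## The synthetic phantom

The generator stands in for clinical data so every claim is testable
against known ground truth. A soft-tissue ellipsoid (LAC 0.02/mm,
water-like) contains two disjoint bone ellipsoids (cortical-like 0.06/mm)
of unequal volume, each with an off-centre lower-attenuation medullary core
(0.03/mm) and an asymmetric bony process. Both asymmetries are load-bearing:
a plain homogeneous ellipsoid projects to a near-identical ellipse under
many 3D rotations, which makes single-view pose recovery genuinely
ill-posed. Cameras sit on a circular orbit (source-to-isocentre 500 mm,
source-to-detector 1000 mm, 64x64 detector at 2 mm pixels by default),
placed equiangularly and inclusively over the requested span: two views
spanning 30 degrees are 30 degrees apart (the limited-angle setting);
sparse-view studies span 180 degrees.

Ground-truth motion samples, per bone, a uniformly random rotation axis and
angle (up to the rotation bound) and translation direction and magnitude
(up to the translation bound). Two deliberate generator properties:

* **Realizability.** The ground-truth field is built with the same weight
  mode the registration will use, so the optimum is exactly attainable and
  parameter recovery is a sharp test (identity recovery returns exactly
  zero twists; two-view recovery lands within ~0.03 degrees / 0.005 mm).
  A `piecewise` mode instead moves each bone rigidly on its own for a
  harder, model-mismatch test.
* **Plausible motion.** Direct log-Euclidean fusion is not a flow
  integration, and bones driven hard *into* each other (antiparallel
  near-bound translations across a small gap) produce a genuinely
  self-intersecting fused field — we reproduce this with worst-case
  motions. Real articulated anatomy does not interpenetrate, so the
  generator rejects and resamples such draws (about 4% of uniform draws at
  the default geometry); the accepted population has fold-free ground
  truth by construction, and cases remain deterministic given the seed.

What the phantom does *not* emulate: detector noise, scatter, beam
hardening, polychromatic spectra, intensity calibration error, anatomical
texture, and segmentation errors beyond the erosion study. Passing tests
therefore demonstrate the correctness and conditioning of the method under
its own forward model, not clinical performance.

## Metrics

Recovery is summarized by per-structure pose errors (geodesic rotation
angle; mean displacement discrepancy over the structure's voxels), Dice
overlap of the moving labelmap warped by the estimated versus the
ground-truth field (nearest-neighbour resampling), and the 95th-percentile
symmetric Hausdorff distance (directed boundary distances pooled from both
masks, linear-interpolated percentile, physical units). Deformation
topology uses the Jacobian of the mapping by central differences on
interior voxels: the percentage of non-positive determinants (%Folds,
counting det <= 0, the conservative reading) and the standard deviation of
the log-determinant over positive voxels. 2D silhouettes threshold a
rendered thickness map at half the minimum voxel spacing; the silhouette
rim is blurred by about one voxel of grazing-ray ramp, so silhouette areas
converge to the analytic projection as resolution grows.

## Study sizes and runtimes

The shipped experiments are sized for a single CPU: the limited-angle
recovery suite runs five seeds on the default 64-cube phantom with two
64x64 views (about 45 s per seed); the weight-function ablation, sparse-view
trend (2, 4 and 8 views over 180 degrees) and 2 mm label-erosion
robustness studies use 48-cube phantoms; the dense translation-field
comparator runs at 32 cubes, where its per-voxel parameterization folds on
over 10% of voxels while the polyrigid field stays fold-free.

## Known limitations

* The dense comparator is deliberately minimal (plain Adam on per-voxel
  translations, optional diffusion penalty). Without multiresolution
  machinery it only feels gradients within one feature scale, so unlike
  full radiotherapy pipelines it converges below the polyrigid model's
  training similarity on these phantoms; its memorization is instead
  exposed by its train-versus-held-out similarity gap.
* Direct fusion guarantees smoothness but not diffeomorphism for arbitrary
  inputs; the plausible-motion population above is where the zero-fold
  property holds (and is the regime the method targets).
* Single-view camera registration of smooth, texture-poor anatomy is
  ill-conditioned in depth and out-of-plane rotation at desk-scale
  resolution regardless of optimizer; the full-volume default and the
  phantom's asymmetries are what make the shipped experiments
  well-conditioned.
* Motions whose rotation approaches 180 degrees are outside the logarithm's
  domain and are rejected rather than special-cased; registration twists
  are far from this regime.
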