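#' @include polyrigid-package.R
NULL

.isFinite3 <- function(x) length(x) == 3L && all(is.finite(x))

#' Volume: a 3D grid of linear attenuation coefficients
#'
#' Values are in 1/mm on a regular lattice. World coordinates are in
#' millimetres; voxel indices are 0-based and a voxel's world position is its
#' centre, so the voxel-to-world map is `x_world = origin + index * spacing`.
#'
#' @slot values 3D numeric array of attenuation coefficients (1/mm).
#' @slot spacing numeric(3), voxel spacing in mm (strictly positive).
#' @slot origin numeric(3), world position of voxel (0,0,0) in mm.
#' @exportClass Volume
setClass("Volume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (!.isFinite3(object@spacing) || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (!.isFinite3(object@origin))
      msg <- c(msg, "origin must be 3 finite values")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' Labelmap: integer structure labels on a Volume lattice
#'
#' Structure ids are 1..K, background is 0. Structures are disjoint by
#' construction of the integer labels.
#'
#' @slot values 3D integer array of labels.
#' @slot spacing,origin as in [Volume-class].
#' @exportClass Labelmap
setClass("Labelmap",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (!is.integer(object@values))
      msg <- c(msg, "labels must be stored as integers")
    if (any(object@values < 0L, na.rm = TRUE))
      msg <- c(msg, "labels must be non-negative")
    if (!.isFinite3(object@spacing) || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (!.isFinite3(object@origin))
      msg <- c(msg, "origin must be 3 finite values")
    if (is.null(msg)) TRUE else msg
  }
)

#' Camera: pinhole projection geometry of one X-ray view
#'
#' The intrinsic matrix is `K = [[f/sx, 0, cx], [0, f/sy, cy], [0, 0, 1]]`
#' with focal length `f` (mm), detector pixel spacings `(sx, sy)` (mm) and
#' principal point `(cx, cy)` in 0-based pixel units. The extrinsic 4x4
#' matrix maps world to camera coordinates; the source position
#' `S = -R^T t` satisfies `R S + t = 0`.
#'
#' @slot intrinsic 3x3 upper-triangular matrix with positive diagonal.
#' @slot extrinsic 4x4 rigid world-to-camera matrix.
#' @slot detectorShape integer(2), pixels along detector x and y.
#' @slot pixelSpacing numeric(2), detector pixel spacing in mm.
#' @exportClass Camera
setClass("Camera",
  representation(intrinsic = "matrix", extrinsic = "matrix",
                 detectorShape = "integer", pixelSpacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    K <- object@intrinsic
    if (!all(dim(K) == c(3, 3)) || any(K[lower.tri(K)] != 0) ||
        any(diag(K) <= 0))
      msg <- c(msg, "intrinsic must be 3x3 upper-triangular with positive diagonal")
    ok <- tryCatch({ .checkRigid(object@extrinsic); TRUE },
                   error = function(e) FALSE)
    if (!ok) msg <- c(msg, "extrinsic is not a rigid transform")
    if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
      msg <- c(msg, "detectorShape must be 2 positive integers")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
      msg <- c(msg, "pixelSpacing must be 2 positive values")
    if (is.null(msg)) TRUE else msg
  }
)

#' RenderConfig: quadrature settings for DRR rendering
#'
#' With `nSamples = 0` the number of quadrature points per ray is chosen from
#' `stepMm` (target spacing between adjacent samples, in mm, measured along
#' the clipped ray); otherwise exactly `nSamples >= 2` points are used per
#' ray. With `clipToVolume` (the default) rays are first intersected with the
#' support box of the zero-padded trilinear interpolant so quadrature is
#' concentrated where the volume is non-zero.
#'
#' @slot nSamples integer, fixed sample count per ray (0 = derive from step).
#' @slot stepMm target step length in mm (> 0).
#' @slot clipToVolume logical flag.
#' @exportClass RenderConfig
setClass("RenderConfig",
  representation(nSamples = "integer", stepMm = "numeric",
                 clipToVolume = "logical"),
  prototype(nSamples = 0L, stepMm = NA_real_, clipToVolume = TRUE),
  validity = function(object) {
    msg <- NULL
    if (object@nSamples != 0L && object@nSamples < 2L)
      msg <- c(msg, "nSamples must be 0 or >= 2")
    if (!is.na(object@stepMm) && object@stepMm <= 0)
      msg <- c(msg, "stepMm must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' SimilarityConfig: multiscale patchwise NCC settings
#'
#' @slot patchSize odd patch side length in pixels (>= 3).
#' @slot scales integer decimation factors (1 = full resolution).
#' @slot useSobel include signed Sobel-x and Sobel-y gradient channels.
#' @exportClass SimilarityConfig
setClass("SimilarityConfig",
  representation(patchSize = "integer", scales = "integer",
                 useSobel = "logical"),
  prototype(patchSize = 13L, scales = c(1L, 2L), useSobel = TRUE),
  validity = function(object) {
    msg <- NULL
    if (object@patchSize < 3L || object@patchSize %% 2L == 0L)
      msg <- c(msg, "patchSize must be odd and >= 3")
    if (length(object@scales) < 1L || any(object@scales < 1L))
      msg <- c(msg, "scales must be non-empty positive integers")
    if (is.null(msg)) TRUE else msg
  }
)

#' OptimConfig: settings for Adam pose optimization
#'
#' Separate step sizes are applied to the rotational (first three) and
#' translational (last three) twist components. Optimization stops when the
#' best objective value improves by less than `plateauTol` (relative) over
#' `plateauWindow` iterations at the smallest learning-rate scale; on a
#' plateau the learning rate is first decayed by `lrDecay` down to
#' `minLrScale` for fine convergence.
#'
#' @slot stepRot learning rate for rotational components (radians).
#' @slot stepXyz learning rate for translational components (mm).
#' @slot maxIters maximum number of iterations (>= 1).
#' @slot plateauTol relative improvement threshold.
#' @slot plateauWindow window length in iterations.
#' @slot lrDecay multiplicative decay on plateau.
#' @slot minLrScale smallest learning-rate scale before stopping.
#' @slot seed integer seed for any stochastic choice.
#' @exportClass OptimConfig
setClass("OptimConfig",
  representation(stepRot = "numeric", stepXyz = "numeric", maxIters = "integer",
                 plateauTol = "numeric", plateauWindow = "integer",
                 lrDecay = "numeric", minLrScale = "numeric", seed = "integer"),
  prototype(stepRot = 1e-2, stepXyz = 1e0, maxIters = 300L, plateauTol = 1e-5,
            plateauWindow = 20L, lrDecay = 0.5, minLrScale = 0.1, seed = 0L),
  validity = function(object) {
    msg <- NULL
    if (object@stepRot <= 0 || object@stepXyz <= 0)
      msg <- c(msg, "step sizes must be positive")
    if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' StructureSet: masks, masses and distance maps of the rigid structures
#'
#' @slot ids integer structure ids (subset of the labelmap's ids).
#' @slot masks list of logical 3D arrays, one per id.
#' @slot masses numeric, non-negative, sums to 1 (voxel count x voxel volume).
#' @slot distanceMaps list of numeric 3D arrays, Euclidean distance (mm) to
#'   each structure; exactly 0 on the structure.
#' @slot dim,spacing,origin lattice geometry shared with the labelmap.
#' @exportClass StructureSet
setClass("StructureSet",
  representation(ids = "integer", masks = "list", masses = "numeric",
                 distanceMaps = "list", dim = "integer", spacing = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@masses < 0) || abs(sum(object@masses) - 1) > 1e-9)
      msg <- c(msg, "masses must be non-negative and sum to 1")
    if (length(object@masks) != length(object@ids) ||
        length(object@distanceMaps) != length(object@ids))
      msg <- c(msg, "masks/distanceMaps must match ids")
    if (is.null(msg)) TRUE else msg
  }
)

#' WeightField: per-voxel convex weights over the rigid structures
#'
#' Each row of `W` (one row per voxel, column-major voxel order) sums to 1.
#' Mode "mass" uses `w_k(x) = m_k / (1 + d_k^2(x))` (hyperparameter-free);
#' mode "reciprocal" uses `w_k(x) = 1 / (1 + eps * d_k^2(x))` with
#' `0 < eps <= 1`.
#'
#' @slot W numeric matrix, voxels x structures, rows sum to 1.
#' @slot mode "mass" or "reciprocal".
#' @slot epsilon decay rate for reciprocal mode (NA for mass mode).
#' @slot ids structure ids corresponding to columns of W.
#' @slot dim,spacing,origin lattice geometry.
#' @exportClass WeightField
setClass("WeightField",
  representation(W = "matrix", mode = "character", epsilon = "numeric",
                 ids = "integer", dim = "integer", spacing = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@mode %in% c("mass", "reciprocal"))
      msg <- c(msg, "mode must be 'mass' or 'reciprocal'")
    if (ncol(object@W) != length(object@ids))
      msg <- c(msg, "W columns must match ids")
    if (nrow(object@W) != prod(object@dim))
      msg <- c(msg, "W rows must match the lattice")
    if (is.null(msg)) TRUE else msg
  }
)

#' PolyrigidField: K rigid transforms fused into a dense deformation
#'
#' The field maps output-lattice coordinates into the input volume's
#' coordinates (a pull-back), so warping evaluates `V(Phi(x))` on the voxel
#' lattice. At any point, `Phi(x) = exp(sum_k W_k(x) log T_k) x`.
#'
#' @slot twists K x 6 matrix of se(3) twists, one row per structure
#'   (rotation components first).
#' @slot weights the [WeightField-class] defining the fusion.
#' @exportClass PolyrigidField
setClass("PolyrigidField",
  representation(twists = "matrix", weights = "WeightField"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@twists) != 6L)
      msg <- c(msg, "twists must have 6 columns")
    if (nrow(object@twists) != length(object@weights@ids))
      msg <- c(msg, "twist rows must match the weight field's structures")
    if (any(!is.finite(object@twists)))
      msg <- c(msg, "twists must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' DenseField: per-voxel translation field (comparator model)
#'
#' @slot disp 4D array (nx, ny, nz, 3) of displacements in mm; the mapping is
#'   `Phi(x) = x + u(x)` in the same pull-back convention as
#'   [PolyrigidField-class].
#' @slot spacing,origin lattice geometry.
#' @exportClass DenseField
setClass("DenseField",
  representation(disp = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@disp)
    if (length(d) != 4L || d[4] != 3L)
      msg <- c(msg, "disp must be (nx, ny, nz, 3)")
    if (any(!is.finite(object@disp)))
      msg <- c(msg, "displacements must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' PhantomConfig: geometry and materials of the synthetic phantom
#'
#' The phantom is a soft-tissue ellipsoid containing K disjoint "bone"
#' ellipsoids of (possibly very) unequal volumes. Each bone has an offset
#' lower-attenuation medullary core so that its projection is asymmetric and
#' rotations are observable. Default attenuations are water-like soft tissue
#' (0.02/mm) and cortical-bone-like (0.06/mm).
#'
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot body list(center, radii) of the soft-tissue ellipsoid (mm).
#' @slot bones list of list(center, radii), one per bone (mm).
#' @slot lacSoft,lacBone,lacMarrow attenuation coefficients (1/mm).
#' @slot seed default seed for case generation.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(gridShape = "integer", spacing = "numeric", body = "list",
                 bones = "list", lacSoft = "numeric", lacBone = "numeric",
                 lacMarrow = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@bones) < 1L) msg <- c(msg, "need at least one bone")
    if (!(object@lacBone > object@lacSoft && object@lacSoft > 0))
      msg <- c(msg, "need lacBone > lacSoft > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' GroundTruthCase: a complete synthetic registration problem
#'
#' Holds the moving volume and labelmap, the ground-truth per-structure
#' twists and polyrigid field, the camera for every view, and the fixed
#' images, which are exactly the DRRs of the warped moving volume.
#'
#' @slot volume,labelmap the moving data.
#' @slot gtTwists K x 6 ground-truth twist matrix.
#' @slot gtField the ground-truth [PolyrigidField-class].
#' @slot cameras list of [Camera-class], one per view.
#' @slot images list of fixed images (matrices of negative log-intensity).
#' @slot renderConfig the [RenderConfig-class] used for the fixed images.
#' @slot seed seed used to sample the motion.
#' @exportClass GroundTruthCase
setClass("GroundTruthCase",
  representation(volume = "Volume", labelmap = "Labelmap", gtTwists = "matrix",
                 gtField = "PolyrigidField", cameras = "list", images = "list",
                 renderConfig = "RenderConfig", seed = "integer"))
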