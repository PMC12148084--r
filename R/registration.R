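#' @include optim.R
NULL

# ---- shared forward model -------------------------------------------------

# Precompute everything that does not change during pose optimization.
.renderState <- function(volume, cameras, images, renderCfg) {
  if (length(cameras) < 1L)
    stop("need at least one view", call. = FALSE)
  if (length(images) != length(cameras))
    stop("images and cameras must match", call. = FALSE)
  for (cam in cameras) .checkSourceOutside(volume, cam)
  rays <- lapply(cameras, .detectorRays)
  list(V = as.vector(volume@values), dim = dim(volume@values),
       spacing = volume@spacing, origin = volume@origin,
       X = latticeWorld(volume), rays = rays, images = images,
       step = .resolveStep(volume, renderCfg), nSamples = renderCfg@nSamples,
       clip = renderCfg@clipToVolume,
       shapes = lapply(cameras, function(c) c@detectorShape))
}

# Objective (mean multiscale NCC over views) and its gradient with respect
# to the K x 6 twist matrix, through the adjoint of the renderer, the
# spatial gradient of the trilinear interpolant, and the differential of the
# exponential map on the mixed per-voxel twist (cpp_twist_sens).
.polyrigidFnGrad <- function(state, W, simCfg, wantGrad = TRUE, h = 1e-5) {
  N <- length(state$rays)
  function(theta) {
    theta <- matrix(theta, ncol = 6)
    Xi <- W %*% theta
    phi <- cpp_twist_apply(Xi, state$X)
    if (wantGrad) {
      vg <- cpp_trilinear_valgrad(state$V, state$dim, state$spacing,
                                  state$origin, phi)
      vw <- vg$value
    } else {
      vw <- cpp_trilinear(state$V, state$dim, state$spacing, state$origin,
                          phi)
    }
    val <- 0
    gvol <- if (wantGrad) numeric(length(vw)) else NULL
    for (n in seq_len(N)) {
      r <- state$rays[[n]]
      img <- matrix(cpp_render(vw, state$dim, state$spacing, state$origin,
                               r$src, r$dst, state$step, state$nSamples,
                               state$clip),
                    nrow = state$shapes[[n]][1])
      res <- multiscaleNCC(state$images[[n]], img, simCfg,
                           gradient = wantGrad)
      if (wantGrad) {
        val <- val + res$value / N
        gvol <- gvol + cpp_render_adjoint(state$dim, state$spacing,
                                          state$origin, r$src, r$dst,
                                          state$step, state$nSamples,
                                          state$clip,
                                          as.vector(res$grad)) / N
      } else val <- val + res / N
    }
    if (!wantGrad) return(list(value = val))
    S <- cpp_twist_sens(Xi, state$X, gvol * vg$grad, h)
    list(value = val, grad = as.vector(crossprod(W, S)))
  }
}

# ---- anchor-based camera estimation ---------------------------------------

#' Estimate per-view camera extrinsics by rigid anchor registration
#'
#' For each view independently, maximizes the multiscale NCC between the
#' observed image and a DRR of the volume, over a rigid se(3) perturbation
#' of that view's initial extrinsic matrix. By default the full volume is
#' rendered: the patchwise ZNCC is contrast-invariant, and for a single
#' smooth structure a depth translation is nearly a pure magnification
#' change, so anchor-only rendering leaves depth close to unobservable;
#' the surrounding anatomy's parallax restores it. Set
#' `maskToAnchor = TRUE` to render only the anchor structure (useful when
#' the remaining anatomy has moved grossly between acquisitions).
#' The perturbation is composed on the world side (`T = T0 exp(delta)`), so
#' rotations act about the world origin near the isocenter and the anchor
#' stays on the detector throughout the capture range. Intrinsics are passed
#' through unchanged. Gradients are central finite differences over the 6
#' pose parameters.
#'
#' @param volume a [Volume-class]
#' @param labelmap a [Labelmap-class] on the same lattice
#' @param anchorId id of a structure reliably visible in all views
#' @param images list of observed images (negative log-intensity matrices)
#' @param cameras list of [Camera-class] carrying the initial extrinsics
#'   (must be within the optimizer's capture range)
#' @param simCfg a [SimilarityConfig-class]
#' @param optCfg an [OptimConfig-class]
#' @param renderCfg a [RenderConfig-class]
#' @param maskToAnchor render only the anchor structure instead of the
#'   full volume (default FALSE)
#' @return list with `cameras` (optimized extrinsics) and `reports`
#'   (per-view loss trajectories)
#' @export
registerCamera <- function(volume, labelmap, anchorId, images, cameras,
                           simCfg = similarityConfig(),
                           optCfg = optimConfig(),
                           renderCfg = renderConfig(),
                           maskToAnchor = FALSE) {
  if (!anchorId %in% structureIds(labelmap))
    stop("anchor structure ", anchorId, " not present in the labelmap",
         call. = FALSE)
  vol <- if (maskToAnchor) maskVolume(volume, labelmap, anchorId) else volume
  Vvec <- as.vector(vol@values)
  d <- dim(vol@values)
  step <- .resolveStep(vol, renderCfg)
  h <- c(rep(1e-4, 3), rep(1e-3, 3))
  out <- vector("list", length(cameras))
  reports <- vector("list", length(cameras))
  for (n in seq_along(cameras)) {
    cam0 <- cameras[[n]]
    T0 <- cam0@extrinsic
    fixed <- images[[n]]
    evalPose <- function(delta) {
      cam <- setExtrinsic(cam0, T0 %*% expSE3(delta))
      .checkSourceOutside(vol, cam)
      r <- .detectorRays(cam)
      img <- matrix(cpp_render(Vvec, d, vol@spacing, vol@origin, r$src,
                               r$dst, step, renderCfg@nSamples,
                               renderCfg@clipToVolume),
                    nrow = cam@detectorShape[1])
      multiscaleNCC(fixed, img, simCfg)
    }
    fnGrad <- function(delta) {
      val <- evalPose(delta)
      if (!is.finite(val))
        stop("non-finite camera similarity in view ", n, call. = FALSE)
      g <- numeric(6)
      for (j in 1:6) {
        e <- numeric(6); e[j] <- h[j]
        g[j] <- (evalPose(delta + e) - evalPose(delta - e)) / (2 * h[j])
      }
      list(value = val, grad = g)
    }
    steps <- c(rep(optCfg@stepRot, 3), rep(optCfg@stepXyz, 3))
    res <- .adamAscent(numeric(6), fnGrad, steps, optCfg)
    out[[n]] <- setExtrinsic(cam0, T0 %*% expSE3(res$par))
    reports[[n]] <- list(loss = res$trajectory, accepted = res$accepted,
                         initialValue = res$trajectory[1],
                         finalValue = res$value,
                         iterations = res$iterations)
  }
  list(cameras = out, reports = reports)
}

# ---- joint polyrigid pose optimization ------------------------------------

#' Jointly estimate per-structure rigid poses from 2D views
#'
#' Maximizes the mean multiscale NCC between the observed images and DRRs of
#' the volume warped by the polyrigid field, over all K twists
#' simultaneously, starting from zero twists (identity). Structures not
#' listed in `structureIdsUsed` receive zero twists and are excluded from
#' the weight field.
#'
#' @param volume a [Volume-class] (moving image)
#' @param labelmap a [Labelmap-class] of the rigid structures
#' @param structureIdsUsed ids whose poses are optimized
#' @param images list of observed (fixed) images
#' @param cameras list of [Camera-class], already estimated
#' @param weightsMode `"mass"` or `"reciprocal"`
#' @param epsilon decay rate for reciprocal mode
#' @param simCfg,optCfg,renderCfg configuration objects
#' @return list with `twists` (K x 6), `field` (the estimated
#'   [PolyrigidField-class]), and `report` (loss trajectory, per-structure
#'   final poses, iteration count)
#' @export
registerPolyrigid <- function(volume, labelmap,
                              structureIdsUsed = structureIds(labelmap),
                              images, cameras, weightsMode = "mass",
                              epsilon = NULL,
                              simCfg = similarityConfig(),
                              optCfg = optimConfig(),
                              renderCfg = renderConfig()) {
  if (length(structureIdsUsed) < 1L)
    stop("need at least one structure to optimize", call. = FALSE)
  ss <- structureSet(labelmap, ids = structureIdsUsed)
  W <- buildWeights(ss, mode = weightsMode, epsilon = epsilon)
  state <- .renderState(volume, cameras, images, renderCfg)
  fnGrad <- .polyrigidFnGrad(state, W@W, simCfg)
  K <- length(W@ids)
  steps <- as.vector(matrix(c(rep(optCfg@stepRot, 3 * K),
                              rep(optCfg@stepXyz, 3 * K)), K, 6))
  res <- .adamAscent(numeric(6L * K), fnGrad, steps, optCfg)
  twists <- matrix(res$par, K, 6)
  rownames(twists) <- W@ids
  poses <- lapply(seq_len(K), function(k) expSE3(twists[k, ]))
  names(poses) <- W@ids
  list(twists = twists, field = buildField(W, twists),
       report = list(loss = res$trajectory, accepted = res$accepted,
                     initialValue = res$trajectory[1], finalValue = res$value,
                     poses = poses, iterations = res$iterations))
}

#' Gradient of the polyrigid objective at a given twist table
#'
#' Exposes the analytic-adjoint gradient used by [registerPolyrigid()];
#' useful for diagnostics and for validating the gradient path against
#' finite differences.
#'
#' @inheritParams registerPolyrigid
#' @param twists K x 6 twist matrix at which to evaluate
#' @return list with `value` and `grad` (K x 6)
#' @export
polyrigidObjective <- function(volume, labelmap,
                               structureIdsUsed = structureIds(labelmap),
                               images, cameras, twists,
                               weightsMode = "mass", epsilon = NULL,
                               simCfg = similarityConfig(),
                               renderCfg = renderConfig(),
                               gradient = TRUE) {
  ss <- structureSet(labelmap, ids = structureIdsUsed)
  W <- buildWeights(ss, mode = weightsMode, epsilon = epsilon)
  state <- .renderState(volume, cameras, images, renderCfg)
  fn <- .polyrigidFnGrad(state, W@W, simCfg, wantGrad = gradient)
  res <- fn(as.vector(rbind(twists)))
  if (gradient) res$grad <- matrix(res$grad, ncol = 6)
  res
}
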