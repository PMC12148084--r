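#' @include metrics.R
NULL

#' Phantom configuration
#'
#' The default phantom is a 64 cubed, 1 mm isotropic grid holding a
#' soft-tissue ellipsoid with two disjoint bone ellipsoids of unequal
#' volume; each bone carries an off-centre lower-attenuation medullary core
#' so its projections are asymmetric and rotations are observable.
#'
#' @param gridShape integer(3) grid dimensions
#' @param spacing numeric(3) voxel spacing (mm)
#' @param body list(center, radii) of the soft-tissue ellipsoid (mm, world)
#' @param bones list of list(center, radii), one entry per bone
#' @param lacSoft,lacBone,lacMarrow linear attenuation coefficients (1/mm)
#' @param seed default seed for case generation
#' @return a [PhantomConfig-class]
#' @export
phantomConfig <- function(gridShape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                          body = list(center = c(0, 0, 0),
                                      radii = c(26, 24, 26)),
                          bones = list(
                            list(center = c(-12, -2, 0), radii = c(5, 8, 10)),
                            list(center = c(13, 2, 0), radii = c(4, 5, 6))),
                          lacSoft = 0.02, lacBone = 0.06, lacMarrow = 0.03,
                          seed = 0L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), body = body, bones = bones,
      lacSoft = lacSoft, lacBone = lacBone, lacMarrow = lacMarrow,
      seed = as.integer(seed))
}

.insideEllipsoid <- function(X, center, radii) {
  rowSums(sweep(sweep(X, 2, center), 2, radii, "/")^2) <= 1
}

#' Generate the phantom volume and labelmap
#'
#' Deterministic given the configuration. Bone attenuation is present only
#' inside labelled voxels; overlapping bones or bones extending beyond the
#' grid raise a configuration error.
#'
#' @param cfg a [PhantomConfig-class]
#' @return list with `volume` ([Volume-class]) and `labelmap`
#'   ([Labelmap-class])
#' @export
generatePhantom <- function(cfg) {
  d <- cfg@gridShape
  origin <- -(d - 1) / 2 * cfg@spacing
  X <- .latticeWorld(d, cfg@spacing, origin)
  lo <- origin - cfg@spacing / 2
  hi <- origin + (d - 0.5) * cfg@spacing
  vals <- numeric(nrow(X))
  labels <- integer(nrow(X))
  vals[.insideEllipsoid(X, cfg@body$center, cfg@body$radii)] <- cfg@lacSoft
  for (k in seq_along(cfg@bones)) {
    b <- cfg@bones[[k]]
    ext <- b$radii * c(1, 1.2, 1)  # includes the bony process
    if (any(b$center - ext < lo) || any(b$center + ext > hi))
      stop("bone ", k, " extends beyond the grid", call. = FALSE)
    inside <- .insideEllipsoid(X, b$center, b$radii)
    # bony process (protrusion): makes the outline rotation-dependent, so
    # poses are observable from projections (an ellipsoid alone projects to
    # a near-identical ellipse under many 3D rotations)
    procCenter <- b$center + c(0, 0.75 * b$radii[2], 0.5 * b$radii[3])
    inside <- inside | .insideEllipsoid(X, procCenter, 0.45 * b$radii)
    if (any(labels[inside] != 0L))
      stop("bones overlap (bone ", k, ")", call. = FALSE)
    labels[inside] <- k
    vals[inside] <- cfg@lacBone
    # off-centre medullary core
    marrowCenter <- b$center + c(0.25 * b$radii[1], 0, 0)
    marrow <- inside & .insideEllipsoid(X, marrowCenter, 0.45 * b$radii)
    vals[marrow] <- cfg@lacMarrow
  }
  list(volume = Volume(array(vals, d), cfg@spacing, origin),
       labelmap = Labelmap(array(labels, d), cfg@spacing, origin))
}

#' Cameras on a circular orbit around the volume isocentre
#'
#' Sources lie on a circle of radius `sid` in the world x-y plane, looking
#' at the isocentre; the detector sits at distance `sdd` from the source.
#' Views are placed at `nViews` equiangular positions spanning
#' `angularSpanDeg` inclusively, so two views with a span of 30 degrees are
#' 30 degrees apart.
#'
#' @param isocenter numeric(3) world isocentre (mm)
#' @param nViews number of views
#' @param angularSpanDeg total angular span (degrees)
#' @param sid source-to-isocentre distance (mm)
#' @param sdd source-to-detector distance (mm)
#' @param detectorShape integer(2) detector pixels
#' @param pixelSpacing numeric(2) detector pixel spacing (mm)
#' @param startDeg angle of the first view
#' @return list of [Camera-class]
#' @export
orbitCameras <- function(isocenter = c(0, 0, 0), nViews = 2,
                         angularSpanDeg = 30, sid = 500, sdd = 1000,
                         detectorShape = c(64L, 64L), pixelSpacing = c(2, 2),
                         startDeg = 0) {
  angles <- if (nViews == 1) startDeg else
    startDeg + seq(0, angularSpanDeg, length.out = nViews)
  lapply(angles * pi / 180, function(th) {
    S <- isocenter + sid * c(cos(th), sin(th), 0)
    zhat <- (isocenter - S) / sqrt(sum((isocenter - S)^2))
    yhat <- c(0, 0, 1)
    xhat <- c(yhat[2] * zhat[3] - yhat[3] * zhat[2],
              yhat[3] * zhat[1] - yhat[1] * zhat[3],
              yhat[1] * zhat[2] - yhat[2] * zhat[1])
    R <- rbind(xhat, yhat, zhat)
    T <- diag(4)
    T[1:3, 1:3] <- R
    T[1:3, 4] <- -R %*% S
    Camera(extrinsic = T, detectorShape = detectorShape,
           pixelSpacing = pixelSpacing, focalLengthMm = sdd)
  })
}

# Sample a rigid motion: uniformly distributed rotation axis and translation
# direction, magnitudes uniform within the stated bounds.
.sampleRigid <- function(maxRotDeg, maxTransMm) {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  angle <- runif(1, 0, maxRotDeg) * pi / 180
  tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
  tmag <- runif(1, 0, maxTransMm)
  T <- expSE3(c(axis * angle, 0, 0, 0))
  T[1:3, 4] <- tdir * tmag
  T
}

#' Generate a complete synthetic registration case
#'
#' Samples ground-truth per-bone rigid motions uniformly within the stated
#' bounds (seeded), builds the ground-truth polyrigid field with the same
#' weight mode the registration will use (so the optimum is attainable and
#' parameter recovery is a sharp test), places cameras equiangularly over
#' the requested span, and renders the fixed images from the warped volume.
#' With `gtMode = "piecewise"` the warped volume instead moves each bone
#' rigidly on its own (soft tissue still follows the polyrigid field),
#' giving a harder, model-mismatch case.
#'
#' @param cfg a [PhantomConfig-class]
#' @param maxRotDeg,maxTransMm per-bone motion bounds (degrees / mm);
#'   scalars are recycled over bones, so e.g. `maxRotDeg = c(0, 10)` keeps
#'   the first (anchor) structure static
#' @param nViews number of X-ray views
#' @param angularSpanDeg angular span of the views: about 30 for the
#'   limited-angle setting, 180 for the sparse-view orbit
#' @param weightsMode,epsilon weight-field construction (see
#'   [buildWeights()])
#' @param seed seed for the motion sampling (defaults to the config's)
#' @param detectorShape,pixelSpacing,sid,sdd camera geometry
#' @param renderCfg a [RenderConfig-class] for the fixed images; the default
#'   uses 1 mm quadrature steps (one voxel of the default phantom), which for
#'   the phantom's smooth ellipsoids is well within the converged regime.
#'   Register against the case with the same configuration so the optimum is
#'   exactly attainable.
#' @param gtMode `"polyrigid"` (realizable) or `"piecewise"`
#' @return a [GroundTruthCase-class]
#' @export
generateCase <- function(cfg, maxRotDeg = 10, maxTransMm = 10, nViews = 2,
                         angularSpanDeg = 30, weightsMode = "mass",
                         epsilon = NULL, seed = cfg@seed,
                         detectorShape = c(64L, 64L), pixelSpacing = c(2, 2),
                         sid = 500, sdd = 1000,
                         renderCfg = renderConfig(stepMm = 1),
                         gtMode = "polyrigid") {
  ph <- generatePhantom(cfg)
  K <- length(cfg@bones)
  ss <- structureSet(ph$labelmap)
  W <- buildWeights(ss, mode = weightsMode, epsilon = epsilon)
  box <- .supportBox(ph$volume)
  set.seed(seed)
  # Sample motions from the anatomically plausible population: bones that
  # translate hard into each other produce self-intersecting (folding)
  # fused fields, which real articulated motion does not; such draws are
  # rejected and resampled (the RNG stream continues, so the case is still
  # deterministic given the seed).
  for (attempt in seq_len(50L)) {
    twists <- matrix(0, K, 6)
    transforms <- vector("list", K)
    rotBound <- rep_len(maxRotDeg, K)
    transBound <- rep_len(maxTransMm, K)
    for (k in seq_len(K)) {
      transforms[[k]] <- .sampleRigid(rotBound[k], transBound[k])
      twists[k, ] <- logSE3(transforms[[k]])
    }
    # FOV check: bone k appears at T_k^{-1} S_k under the pull-back field
    for (k in seq_len(K)) {
      mask <- ph$labelmap@values == k
      idx <- which(mask, arr.ind = TRUE) - 1
      lo <- apply(idx, 2, min) * cfg@spacing + ph$volume@origin
      hi <- apply(idx, 2, max) * cfg@spacing + ph$volume@origin
      corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                       c(lo[3], hi[3])))
      moved <- cbind(corners, 1) %*% t(solve(transforms[[k]]))
      if (any(moved[, 1:3] < matrix(box$lo, 8, 3, byrow = TRUE)) ||
          any(moved[, 1:3] > matrix(box$hi, 8, 3, byrow = TRUE)))
        stop("sampled motion pushes bone ", k,
             " outside the field of view; reduce the motion bounds",
             call. = FALSE)
    }
    gtField <- buildField(W, twists)
    if (jacobianStats(gtField)$percentFolds == 0) break
    if (attempt == 50L)
      stop("could not sample a non-interpenetrating motion within the ",
           "given bounds", call. = FALSE)
  }
  warped <- if (identical(gtMode, "piecewise")) {
    .piecewiseWarp(ph$volume, ph$labelmap, transforms, gtField)
  } else {
    warpVolume(ph$volume, gtField)
  }
  cameras <- orbitCameras(isocenter = c(0, 0, 0), nViews = nViews,
                          angularSpanDeg = angularSpanDeg, sid = sid,
                          sdd = sdd, detectorShape = detectorShape,
                          pixelSpacing = pixelSpacing)
  images <- lapply(cameras, function(cam) renderDRR(warped, cam, renderCfg))
  new("GroundTruthCase", volume = ph$volume, labelmap = ph$labelmap,
      gtTwists = twists, gtField = gtField, cameras = cameras,
      images = images, renderConfig = renderCfg, seed = as.integer(seed))
}

# Model-mismatch ground truth: each bone moves rigidly on its own (the voxel
# shows bone k where T_k x lands inside S_k), soft tissue follows the
# polyrigid field.
.piecewiseWarp <- function(volume, labelmap, transforms, gtField) {
  X <- latticeWorld(volume)
  vals <- as.vector(warpVolume(volume, gtField)@values)
  d <- dim(volume@values)
  claimed <- logical(nrow(X))
  for (k in seq_along(transforms)) {
    Tk <- transforms[[k]]
    Xk <- cbind(X, 1) %*% t(Tk)
    lab <- cpp_nearest(as.vector(labelmap@values), d, labelmap@spacing,
                       labelmap@origin, Xk[, 1:3, drop = FALSE])
    inK <- lab == k & !claimed
    vals[inK] <- cpp_trilinear(as.vector(volume@values), d, volume@spacing,
                               volume@origin, Xk[inK, 1:3, drop = FALSE])
    claimed <- claimed | inK
  }
  Volume(array(vals, d), volume@spacing, volume@origin)
}

#' Write a full case to disk (volume, labels, geometry, views, field)
#'
#' @param case a [GroundTruthCase-class]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(case@volume, file.path(dir, "volume.nii.gz"))
  writeVolume(case@labelmap, file.path(dir, "labels.nii.gz"))
  writeTwists(case@gtTwists, file.path(dir, "gt_twists.json"),
              ids = case@gtField@weights@ids)
  writeGeometry(case@cameras, file.path(dir, "geometry.json"))
  viewDir <- file.path(dir, "views")
  dir.create(viewDir, showWarnings = FALSE)
  for (n in seq_along(case@images))
    writeProjection(case@images[[n]],
                    file.path(viewDir, sprintf("view_%02d.tiff", n)))
  writeField(case@gtField, file.path(dir, "gt_field.nii.gz"))
  invisible(dir)
}
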