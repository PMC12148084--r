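#' @include camera.R
NULL

#' Rendering configuration
#'
#' @param nSamples fixed quadrature points per ray (0 = derive from step)
#' @param stepMm target step length in mm; defaults at render time to half
#'   the minimum voxel spacing
#' @param clipToVolume intersect rays with the volume support box first
#' @return a [RenderConfig-class]
#' @export
renderConfig <- function(nSamples = 0L, stepMm = NA_real_,
                         clipToVolume = TRUE) {
  new("RenderConfig", nSamples = as.integer(nSamples),
      stepMm = as.numeric(stepMm), clipToVolume = clipToVolume)
}

.supportBox <- function(v) {
  list(lo = v@origin - v@spacing,
       hi = v@origin + dim(v@values) * v@spacing)
}

.resolveStep <- function(v, cfg) {
  if (!is.na(cfg@stepMm)) cfg@stepMm else min(v@spacing) / 2
}

.checkSourceOutside <- function(v, camera) {
  S <- sourcePosition(camera)
  box <- .supportBox(v)
  if (all(S > box$lo & S < box$hi))
    stop("X-ray source lies inside the volume; ray chords are undefined",
         call. = FALSE)
  invisible(TRUE)
}

#' Render a digitally reconstructed radiograph (DRR)
#'
#' Implements the Beer-Lambert line integral with interpolating quadrature:
#' each ray `r(lambda) = S + lambda (P - S)` is sampled at M uniformly spaced
#' points and the pixel holds
#' `||P - S|| * sum_m V[r(lambda_m)] (lambda_{m+1} - lambda_m)`.
#' Pixel values are negative log-intensities (line integrals, 1 = unit
#' attenuation path), never exponentiated, and are linear in the volume.
#'
#' @param v a [Volume-class] of linear attenuation coefficients
#' @param camera a [Camera-class]
#' @param cfg a [RenderConfig-class]
#' @return matrix of negative log-intensities with dim `detectorShape`
#' @export
renderDRR <- function(v, camera, cfg = renderConfig()) {
  .checkSourceOutside(v, camera)
  rays <- .detectorRays(camera)
  vals <- cpp_render(as.vector(v@values), dim(v@values), v@spacing, v@origin,
                     rays$src, rays$dst, .resolveStep(v, cfg), cfg@nSamples,
                     cfg@clipToVolume)
  matrix(vals, nrow = camera@detectorShape[1])
}

#' Render only selected structures of a volume
#'
#' Renders the volume with all voxels outside the selected structures set to
#' 0; used for anchor-based camera registration and silhouette metrics.
#'
#' @param v a [Volume-class]
#' @param lm a [Labelmap-class] on the same lattice
#' @param ids structure ids to keep
#' @inheritParams renderDRR
#' @return matrix of negative log-intensities
#' @export
renderStructure <- function(v, lm, ids, camera, cfg = renderConfig()) {
  vals <- maskVolume(v, lm, ids)
  renderDRR(vals, camera, cfg)
}

#' Zero a volume outside selected structures
#' @inheritParams renderStructure
#' @return a masked [Volume-class]
#' @export
maskVolume <- function(v, lm, ids) {
  if (!all(dim(v@values) == dim(lm@values)))
    stop("volume and labelmap lattices differ", call. = FALSE)
  ids <- as.integer(ids)
  known <- structureIds(lm)
  bad <- setdiff(ids, c(known, 0L))
  if (length(bad))
    stop("unknown structure id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals <- v@values
  vals[!(lm@values %in% ids)] <- 0
  Volume(vals, v@spacing, v@origin)
}

#' Analytic pose gradient of a single DRR pixel
#'
#' Computes the derivative of one pixel of
#' `renderDRR(warpVolume(v, rigid field exp(xi)), camera)` with respect to
#' the 6 twist components, through the adjoint of the renderer, the spatial
#' gradient of the trilinear interpolant, and the differential of the
#' exponential map. Used to validate the gradient path of the registration
#' objective against finite differences.
#'
#' @param v a [Volume-class]
#' @param camera a [Camera-class]
#' @param cfg a [RenderConfig-class]
#' @param xi length-6 twist at which to differentiate
#' @param pixel integer(2), 1-based pixel index on the detector
#' @return list with `value` (the pixel's intensity) and `gradient`
#'   (length-6 twist gradient)
#' @export
drrPixelPoseGradient <- function(v, camera, cfg, xi, pixel) {
  d <- dim(v@values)
  X <- latticeWorld(v)
  Xi <- matrix(rep(xi, each = nrow(X)), ncol = 6)
  phi <- cpp_twist_apply(Xi, X)
  vw <- cpp_trilinear(as.vector(v@values), d, v@spacing, v@origin, phi)
  rays <- .detectorRays(camera)
  step <- .resolveStep(v, cfg)
  img <- cpp_render(vw, d, v@spacing, v@origin, rays$src, rays$dst, step,
                    cfg@nSamples, cfg@clipToVolume)
  pidx <- pixel[1] + camera@detectorShape[1] * (pixel[2] - 1)
  gpix <- numeric(length(img))
  gpix[pidx] <- 1
  gvol <- cpp_render_adjoint(d, v@spacing, v@origin, rays$src, rays$dst,
                             step, cfg@nSamples, cfg@clipToVolume, gpix)
  gV <- cpp_trilinear_grad(as.vector(v@values), d, v@spacing, v@origin, phi)
  base <- gvol * gV
  h <- 1e-5
  grad <- numeric(6)
  for (j in 1:6) {
    e <- numeric(6); e[j] <- h
    dphi <- (cpp_twist_apply(sweep(Xi, 2, e, "+"), X) -
             cpp_twist_apply(sweep(Xi, 2, e, "-"), X)) / (2 * h)
    grad[j] <- sum(base * dphi)
  }
  list(value = img[pidx], gradient = grad)
}
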