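#' @include registration.R
NULL

# Forward differences of u along one voxel axis (4D array in, 4D array out).
.axisDiff <- function(uArr, axis) {
  n <- dim(uArr)[axis]
  switch(axis,
         uArr[2:n, , , , drop = FALSE] - uArr[1:(n - 1), , , , drop = FALSE],
         uArr[, 2:n, , , drop = FALSE] - uArr[, 1:(n - 1), , , drop = FALSE],
         uArr[, , 2:n, , drop = FALSE] - uArr[, , 1:(n - 1), , drop = FALSE])
}

# Diffusion penalty P(u) = w * sum_axes sum_x ||u(x+e) - u(x)||^2 and its
# gradient (2w times the graph Laplacian of u).
.diffusionPenalty <- function(uArr, w) {
  if (w == 0) return(0)
  p <- 0
  for (axis in 1:3)
    if (dim(uArr)[axis] >= 2) p <- p + sum(.axisDiff(uArr, axis)^2)
  w * p
}

.diffusionGrad <- function(uArr, w) {
  g <- array(0, dim(uArr))
  for (axis in 1:3) {
    n <- dim(uArr)[axis]
    if (n < 2) next
    diff <- 2 * w * .axisDiff(uArr, axis)
    if (axis == 1) {
      g[1:(n - 1), , , ] <- g[1:(n - 1), , , , drop = FALSE] - diff
      g[2:n, , , ] <- g[2:n, , , , drop = FALSE] + diff
    } else if (axis == 2) {
      g[, 1:(n - 1), , ] <- g[, 1:(n - 1), , , drop = FALSE] - diff
      g[, 2:n, , ] <- g[, 2:n, , , drop = FALSE] + diff
    } else {
      g[, , 1:(n - 1), ] <- g[, , 1:(n - 1), , drop = FALSE] - diff
      g[, , 2:n, ] <- g[, , 2:n, , drop = FALSE] + diff
    }
  }
  g
}

#' Dense per-voxel translation-field registration (comparator)
#'
#' Optimizes an independent 3-vector displacement for every voxel of the
#' moving volume by gradient ascent on the same rendered-similarity
#' objective as [registerPolyrigid()], optionally minus a diffusion
#' (squared forward-difference) smoothness penalty. This deliberately
#' under-constrained model serves to demonstrate the advantage of the
#' polyrigid parameterization under sparse supervision: it tends to memorize
#' the appearance of the training views while producing irregular, folding
#' deformations.
#'
#' @inheritParams registerPolyrigid
#' @param smoothWeight diffusion penalty weight (default 0, the
#'   regularization-free comparison)
#' @return list with `field` (a [DenseField-class]) and `report`
#' @export
registerDense <- function(volume, images, cameras,
                          simCfg = similarityConfig(),
                          optCfg = optimConfig(),
                          renderCfg = renderConfig(),
                          smoothWeight = 0) {
  state <- .renderState(volume, cameras, images, renderCfg)
  d <- dim(volume@values)
  M <- prod(d)
  N <- length(cameras)
  fnGrad <- function(u) {
    uMat <- matrix(u, ncol = 3)
    phi <- state$X + uMat
    vw <- cpp_trilinear(state$V, state$dim, state$spacing, state$origin, phi)
    val <- 0
    gvol <- numeric(M)
    for (n in seq_len(N)) {
      r <- state$rays[[n]]
      img <- matrix(cpp_render(vw, state$dim, state$spacing, state$origin,
                               r$src, r$dst, state$step, state$nSamples,
                               state$clip),
                    nrow = state$shapes[[n]][1])
      res <- multiscaleNCC(state$images[[n]], img, simCfg, gradient = TRUE)
      val <- val + res$value / N
      gvol <- gvol + cpp_render_adjoint(state$dim, state$spacing,
                                        state$origin, r$src, r$dst,
                                        state$step, state$nSamples,
                                        state$clip, as.vector(res$grad)) / N
    }
    gV <- cpp_trilinear_grad(state$V, state$dim, state$spacing, state$origin,
                             phi)
    grad <- gvol * gV
    if (smoothWeight > 0) {
      uArr <- array(u, c(d, 3L))
      val <- val - .diffusionPenalty(uArr, smoothWeight)
      grad <- grad - matrix(.diffusionGrad(uArr, smoothWeight), ncol = 3)
    }
    list(value = val, grad = as.vector(grad))
  }
  res <- .adamAscent(numeric(3 * M), fnGrad, rep(optCfg@stepXyz, 3 * M),
                     optCfg)
  field <- new("DenseField", disp = array(res$par, c(d, 3L)),
               spacing = volume@spacing, origin = volume@origin)
  list(field = field,
       report = list(loss = res$trajectory, accepted = res$accepted,
                     initialValue = res$trajectory[1],
                     finalValue = res$value, iterations = res$iterations))
}
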