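#' @include similarity.R
NULL

#' Optimization configuration
#'
#' Defaults follow standard practice for se(3) pose optimization: Adam with
#' step size 1e-2 (radians) on the rotational and 1e0 (mm) on the
#' translational twist components, a 300-iteration budget, and plateau-based
#' stopping with learning-rate decay for fine convergence.
#'
#' @param stepRot,stepXyz rotational / translational learning rates
#' @param maxIters iteration budget per stage
#' @param plateauTol,plateauWindow relative-improvement plateau criterion
#' @param lrDecay,minLrScale learning-rate decay schedule on plateaus
#' @param seed seed for any stochastic choice (the default pipeline is
#'   deterministic given its inputs)
#' @return an [OptimConfig-class]
#' @export
optimConfig <- function(stepRot = 1e-2, stepXyz = 1e0, maxIters = 300L,
                        plateauTol = 1e-5, plateauWindow = 20L,
                        lrDecay = 0.5, minLrScale = 0.1, seed = 0L) {
  new("OptimConfig", stepRot = stepRot, stepXyz = stepXyz,
      maxIters = as.integer(maxIters), plateauTol = plateauTol,
      plateauWindow = as.integer(plateauWindow), lrDecay = lrDecay,
      minLrScale = minLrScale, seed = as.integer(seed))
}

# Adam gradient ascent with per-parameter step sizes, best-iterate tracking
# (so the returned parameters never score below the initial ones) and
# plateau-triggered learning-rate decay. fnGrad(par) must return
# list(value, grad); both are for the *maximization* objective.
.adamAscent <- function(par, fnGrad, stepSizes, cfg) {
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  m <- numeric(length(par)); v <- numeric(length(par))
  lrScale <- 1
  best <- -Inf; bestPar <- par
  traj <- numeric(0)
  windowBest <- -Inf; windowStart <- 0L
  for (it in seq_len(cfg@maxIters)) {
    fg <- fnGrad(par)
    if (!is.finite(fg$value))
      stop("objective became non-finite during optimization (iteration ",
           it, ")", call. = FALSE)
    traj[it] <- fg$value
    if (fg$value > best) { best <- fg$value; bestPar <- par }
    # plateau bookkeeping on the best-so-far value
    if (it - windowStart >= cfg@plateauWindow) {
      if (best - windowBest < cfg@plateauTol * max(1, abs(best))) {
        lrScale <- lrScale * cfg@lrDecay
        if (lrScale < cfg@minLrScale) break
      }
      windowBest <- best; windowStart <- it
    }
    g <- fg$grad
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^it)
    vh <- v / (1 - beta2^it)
    par <- par + lrScale * stepSizes * mh / (sqrt(vh) + eps)
  }
  list(par = bestPar, value = best, trajectory = traj,
       accepted = cummax(traj), iterations = length(traj))
}
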