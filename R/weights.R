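#' @include render.R
NULL

#' Normalized structure masses from a labelmap
#'
#' Masses are proportional to voxel count times voxel volume (a constant
#' bone-density assumption) and normalized to sum to 1. The normalization
#' cancels in the weight-field ratio but keeps the mass-based and
#' reciprocal-distance weight modes comparable.
#'
#' @param lm a [Labelmap-class]
#' @param ids structure ids to include (default: all present)
#' @return named numeric vector summing to 1
#' @export
computeMasses <- function(lm, ids = structureIds(lm)) {
  ids <- as.integer(ids)
  if (length(ids) < 1L) stop("need at least one structure", call. = FALSE)
  counts <- vapply(ids, function(id) sum(lm@values == id), numeric(1))
  empty <- ids[counts == 0]
  if (length(empty))
    stop("empty structure id(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  m <- counts * prod(lm@spacing)
  stats::setNames(m / sum(m), ids)
}

#' Per-structure Euclidean distance maps
#'
#' Physical-unit (mm) exact Euclidean distance from every voxel to each
#' structure; exactly 0 on the structure, computed with a separable
#' lower-envelope distance transform that honours anisotropic spacing.
#'
#' @inheritParams computeMasses
#' @return list of 3D arrays, one per id
#' @export
computeDistanceMaps <- function(lm, ids = structureIds(lm)) {
  ids <- as.integer(ids)
  d <- dim(lm@values)
  lapply(stats::setNames(ids, ids), function(id) {
    mask <- as.vector(lm@values == id)
    if (!any(mask)) stop("empty structure id: ", id, call. = FALSE)
    array(cpp_edt(mask, d, lm@spacing), d)
  })
}

#' Assemble a StructureSet (masks, masses, distance maps)
#'
#' @inheritParams computeMasses
#' @return a [StructureSet-class]
#' @export
structureSet <- function(lm, ids = structureIds(lm)) {
  ids <- as.integer(ids)
  known <- structureIds(lm)
  bad <- setdiff(ids, known)
  if (length(bad))
    stop("unknown structure id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  masks <- lapply(ids, function(id) lm@values == id)
  new("StructureSet", ids = ids, masks = masks,
      masses = as.numeric(computeMasses(lm, ids)),
      distanceMaps = computeDistanceMaps(lm, ids),
      dim = dim(lm@values), spacing = lm@spacing, origin = lm@origin)
}

#' Build the per-voxel structure weight field
#'
#' In mass mode (hyperparameter-free) the unnormalized weight of structure k
#' is `m_k / (1 + d_k^2(x))` with `m_k` the normalized structure mass; in
#' reciprocal-distance mode it is `1 / (1 + eps * d_k^2(x))` with decay rate
#' `0 < eps <= 1`. Rows are then normalized to sum to 1.
#'
#' @param ss a [StructureSet-class]
#' @param mode `"mass"` or `"reciprocal"`
#' @param epsilon decay rate, required for (and only for) reciprocal mode
#' @return a [WeightField-class]
#' @export
buildWeights <- function(ss, mode = c("mass", "reciprocal"), epsilon = NULL) {
  mode <- match.arg(mode)
  K <- length(ss@ids)
  D <- vapply(ss@distanceMaps, as.vector, numeric(prod(ss@dim)))
  D <- matrix(D, ncol = K)
  if (mode == "mass") {
    if (!is.null(epsilon))
      stop("mass mode is hyperparameter-free; epsilon must not be supplied",
           call. = FALSE)
    W <- sweep(1 / (1 + D^2), 2, ss@masses, "*")
    epsilon <- NA_real_
  } else {
    if (is.null(epsilon) || !is.finite(epsilon) || epsilon <= 0 ||
        epsilon > 1)
      stop("reciprocal mode requires 0 < epsilon <= 1", call. = FALSE)
    W <- 1 / (1 + epsilon * D^2)
  }
  W <- W / rowSums(W)
  new("WeightField", W = W, mode = mode, epsilon = epsilon, ids = ss@ids,
      dim = ss@dim, spacing = ss@spacing, origin = ss@origin)
}
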