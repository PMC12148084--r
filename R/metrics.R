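#' @include dense.R
NULL

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty. Symmetric in its arguments.
#'
#' @param a,b logical arrays on the same lattice
#' @return scalar in `[0, 1]`
#' @export
diceCoefficient <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks must share a lattice", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

# Boundary voxels: in the mask with at least one 6-neighbour outside (the
# volume edge counts as outside).
.boundary <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shrink <- function(m, axis, dir) {
    out <- array(FALSE, d)
    n <- d[axis]
    if (axis == 1) {
      if (dir > 0) out[1:(n - 1), , ] <- m[2:n, , ] else out[2:n, , ] <- m[1:(n - 1), , ]
    } else if (axis == 2) {
      if (dir > 0) out[, 1:(n - 1), ] <- m[, 2:n, ] else out[, 2:n, ] <- m[, 1:(n - 1), ]
    } else {
      if (dir > 0) out[, , 1:(n - 1)] <- m[, , 2:n] else out[, , 2:n] <- m[, , 1:(n - 1)]
    }
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- interior & shrink(mask, axis, dir)
  mask & !interior
}

#' 95th-percentile symmetric Hausdorff distance between two masks
#'
#' Pools the directed boundary-to-boundary nearest distances from both masks
#' and takes the linearly interpolated 95th percentile, in physical units.
#'
#' @param a,b non-empty logical arrays on the same lattice
#' @param spacing numeric(3) voxel spacing in mm
#' @param probs percentile (default 0.95)
#' @return distance in mm
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), probs = 0.95) {
  if (!all(dim(a) == dim(b)))
    stop("masks must share a lattice", call. = FALSE)
  if (!any(a) || !any(b))
    stop("hd95 requires two non-empty masks", call. = FALSE)
  d <- dim(a)
  ba <- .boundary(a); bb <- .boundary(b)
  distToB <- array(cpp_edt(as.vector(bb), d, spacing), d)
  distToA <- array(cpp_edt(as.vector(ba), d, spacing), d)
  pooled <- c(distToB[ba], distToA[bb])
  as.numeric(stats::quantile(pooled, probs = probs, type = 7, names = FALSE))
}

#' Jacobian statistics of a deformation field
#'
#' Computes the Jacobian determinant of the mapping at interior voxels by
#' central finite differences (in mm) and reports the percentage of folds
#' (non-positive determinants, a topology violation) and the standard
#' deviation of the log determinant over voxels with positive determinant
#' (spatial irregularity of volume change).
#'
#' @param field a [PolyrigidField-class], [DenseField-class], or a 4D
#'   mapping array (nx, ny, nz, 3) of world positions
#' @param spacing required when `field` is a bare mapping array
#' @return list with `percentFolds` (0..100) and `sigmaLogJac` (>= 0)
#' @export
jacobianStats <- function(field, spacing = NULL) {
  if (is(field, "PolyrigidField")) {
    phi <- mappingGrid(field)
    spacing <- field@weights@spacing
  } else if (is(field, "DenseField")) {
    phi <- mappingGrid(field)
    spacing <- field@spacing
  } else {
    phi <- field
    if (is.null(spacing)) stop("spacing required for a bare mapping array",
                               call. = FALSE)
  }
  d <- dim(phi)[1:3]
  if (any(d < 3))
    stop("need at least 3 voxels per axis for central differences",
         call. = FALSE)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  J <- vector("list", 3)
  for (axis in 1:3) {
    hh <- 2 * spacing[axis]
    J[[axis]] <- switch(axis,
      (phi[ix + 1, iy, iz, ] - phi[ix - 1, iy, iz, ]) / hh,
      (phi[ix, iy + 1, iz, ] - phi[ix, iy - 1, iz, ]) / hh,
      (phi[ix, iy, iz + 1, ] - phi[ix, iy, iz - 1, ]) / hh)
  }
  a11 <- J[[1]][, , , 1]; a21 <- J[[1]][, , , 2]; a31 <- J[[1]][, , , 3]
  a12 <- J[[2]][, , , 1]; a22 <- J[[2]][, , , 2]; a32 <- J[[2]][, , , 3]
  a13 <- J[[3]][, , , 1]; a23 <- J[[3]][, , , 2]; a33 <- J[[3]][, , , 3]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  pos <- det > 0
  list(percentFolds = 100 * mean(!pos),
       sigmaLogJac = if (any(pos)) stats::sd(log(det[pos])) else 0)
}

#' Project a structure's silhouette onto the detector
#'
#' Renders the structure's binary mask as unit attenuation, giving a
#' thickness map (mm of material along each ray), then thresholds at half
#' the minimum voxel spacing to obtain a binary silhouette.
#'
#' @param lm a [Labelmap-class]
#' @param id structure id
#' @param camera a [Camera-class]
#' @param cfg a [RenderConfig-class]
#' @return logical matrix of the silhouette
#' @export
projectMask <- function(lm, id, camera, cfg = renderConfig()) {
  if (length(id) != 1L || !is.finite(id) || id < 1 || id != round(id))
    stop("invalid structure id: ", id, call. = FALSE)
  # an id with no voxels is an empty structure: its silhouette is empty
  maskVol <- Volume(array(as.numeric(lm@values == id), dim(lm@values)),
                    lm@spacing, lm@origin)
  thickness <- renderDRR(maskVol, camera, cfg)
  thickness > min(lm@spacing) / 2
}

#' Per-structure Dice between two warps of the same labelmap
#'
#' Warps the moving labelmap with an estimated and a reference deformation
#' field (nearest neighbour) and reports Dice per structure; the mean over
#' structures is the standard recovery summary for phantom studies.
#'
#' @param lm the moving [Labelmap-class]
#' @param fieldEst,fieldRef estimated and reference deformation fields
#' @return named numeric vector of Dice values, one per structure
#' @export
warpedMaskDice <- function(lm, fieldEst, fieldRef) {
  est <- warpLabelmap(lm, fieldEst)
  ref <- warpLabelmap(lm, fieldRef)
  ids <- structureIds(lm)
  vapply(stats::setNames(ids, ids), function(id) {
    diceCoefficient(est@values == id, ref@values == id)
  }, numeric(1))
}

#' Rotation and mean target-registration error between two rigid poses
#'
#' The rotation error is the geodesic angle of the relative rotation; the
#' translation error is the mean displacement discrepancy (mm) over a set of
#' evaluation points (typically the structure's voxels).
#'
#' @param Test,Tgt 4x4 rigid transforms (estimated and ground truth)
#' @param points M x 3 world points at which displacement is compared
#' @return list with `rotDeg` and `transMm`
#' @export
poseError <- function(Test, Tgt, points) {
  Rrel <- Test[1:3, 1:3] %*% t(Tgt[1:3, 1:3])
  ct <- max(-1, min(1, (sum(diag(Rrel)) - 1) / 2))
  points <- rbind(points)
  pe <- cbind(points, 1) %*% t(Test - Tgt)
  list(rotDeg = acos(ct) * 180 / pi,
       transMm = mean(sqrt(rowSums(pe[, 1:3, drop = FALSE]^2))))
}
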