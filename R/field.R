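#' @include weights.R
NULL

#' Fuse per-structure rigid transforms into a polyrigid field
#'
#' At every voxel the local transform is the exponential of the
#' weight-averaged twists, `exp(sum_k W_xk log T_k)`, applied to the voxel's
#' homogeneous coordinates. With a single structure this reduces exactly to
#' that rigid transform; with all twists zero the field is the identity.
#'
#' @param W a [WeightField-class]
#' @param twists K x 6 twist matrix (rows = structures, matching W's ids)
#' @return a [PolyrigidField-class]
#' @export
buildField <- function(W, twists) {
  twists <- rbind(twists)
  if (nrow(twists) != ncol(W@W))
    stop("number of twists does not match the weight field's structures",
         call. = FALSE)
  new("PolyrigidField", twists = twists, weights = W)
}

# Mapped world positions at every lattice voxel (M x 3, column-major order).
.fieldMapping <- function(field) {
  w <- field@weights
  X <- .latticeWorld(w@dim, w@spacing, w@origin)
  Xi <- w@W %*% field@twists
  cpp_twist_apply(Xi, X)
}

#' Evaluate a polyrigid field at arbitrary world points
#'
#' Off-lattice points use trilinear interpolation of the normalized weight
#' field (with border replication, so weight rows still sum to 1) followed
#' by the exponential of the interpolated mixed twist: a cheap, continuous
#' extension of the lattice field.
#'
#' @param field a [PolyrigidField-class]
#' @param points M x 3 world coordinates (mm)
#' @return M x 3 mapped world coordinates (mm)
#' @export
fieldAtPoints <- function(field, points) {
  points <- rbind(points)
  w <- field@weights
  # clamp queries to the voxel-centre hull: equivalent to border replication
  clamped <- points
  for (a in 1:3) {
    lo <- w@origin[a]
    hi <- w@origin[a] + (w@dim[a] - 1) * w@spacing[a]
    clamped[, a] <- pmin(pmax(points[, a], lo), hi)
  }
  K <- ncol(w@W)
  Wp <- vapply(seq_len(K), function(k) {
    cpp_trilinear(as.vector(w@W[, k]), w@dim, w@spacing, w@origin, clamped)
  }, numeric(nrow(points)))
  Wp <- matrix(Wp, ncol = K)
  Xi <- Wp %*% field@twists
  cpp_twist_apply(Xi, points)
}

#' @rdname mappingGrid
setMethod("mappingGrid", "PolyrigidField", function(field) {
  w <- field@weights
  array(.fieldMapping(field), c(w@dim, 3L))
})

#' @rdname mappingGrid
setMethod("mappingGrid", "DenseField", function(field) {
  d <- dim(field@disp)[1:3]
  X <- .latticeWorld(d, field@spacing, field@origin)
  array(X + matrix(field@disp, ncol = 3), c(d, 3L))
})

#' @rdname displacementField
setMethod("displacementField", "PolyrigidField", function(field) {
  w <- field@weights
  X <- .latticeWorld(w@dim, w@spacing, w@origin)
  new("DenseField", disp = array(.fieldMapping(field) - X, c(w@dim, 3L)),
      spacing = w@spacing, origin = w@origin)
})

#' @rdname displacementField
setMethod("displacementField", "DenseField", function(field) field)

#' Export a deformation field as a dense displacement NIfTI plus twist JSON
#'
#' Writes the displacement (mm, output-to-input pull-back convention) as a
#' 4D NIfTI with components in the fourth dimension; for polyrigid fields
#' the K twists and structure ids are written alongside as JSON.
#'
#' @param field a [PolyrigidField-class] or [DenseField-class]
#' @param path output `.nii`/`.nii.gz` path
#' @return invisibly, the path
#' @export
writeField <- function(field, path) {
  df <- displacementField(field)
  img <- RNifti::asNifti(df@disp)
  RNifti::pixdim(img) <- c(df@spacing, 1)
  aff <- .affine(df@spacing, df@origin)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  if (is(field, "PolyrigidField"))
    writeTwists(field@twists, sub("\\.nii(\\.gz)?$", ".twists.json", path),
                ids = field@weights@ids)
  invisible(path)
}

#' Read a dense displacement field written by [writeField()]
#' @param path a 4D displacement NIfTI
#' @return a [DenseField-class]
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("expected a (nx, ny, nz, 3) displacement field: ", path,
         call. = FALSE)
  g <- .xformFromImage(img, path)
  new("DenseField", disp = array(as.numeric(a), dim(a)),
      spacing = g$spacing, origin = g$origin)
}
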