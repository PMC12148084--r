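#' @include se3.R
NULL

#' Construct a Volume
#'
#' @param values 3D numeric array of linear attenuation coefficients (1/mm)
#' @param spacing numeric(3) voxel spacing in mm
#' @param origin numeric(3) world position of voxel (0,0,0); the default
#'   centres the volume on the world origin
#' @return a [Volume-class]
#' @export
Volume <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  new("Volume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a Labelmap
#'
#' @param labels 3D integer array (0 = background, 1..K = structures)
#' @param spacing,origin as in [Volume()]
#' @return a [Labelmap-class]
#' @export
Labelmap <- function(labels, spacing = c(1, 1, 1), origin = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (is.null(origin)) origin <- -(dim(labels) - 1) / 2 * spacing
  new("Labelmap", values = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Structure ids present in a labelmap
#' @param lm a [Labelmap-class]
#' @return sorted integer vector of non-zero labels
#' @export
structureIds <- function(lm) {
  sort(setdiff(unique(as.vector(lm@values)), 0L))
}

# World coordinates of all voxel centres, column-major voxel order (M x 3).
.latticeWorld <- function(dim, spacing, origin) {
  i <- (seq_len(dim[1]) - 1) * spacing[1] + origin[1]
  j <- (seq_len(dim[2]) - 1) * spacing[2] + origin[2]
  k <- (seq_len(dim[3]) - 1) * spacing[3] + origin[3]
  cbind(rep(i, times = dim[2] * dim[3]),
        rep(rep(j, each = dim[1]), times = dim[3]),
        rep(k, each = dim[1] * dim[2]))
}

latticeWorld <- function(x) .latticeWorld(dim(x@values), x@spacing, x@origin)

# ---- NIfTI-1 I/O ----------------------------------------------------------

.xformFromImage <- function(img, path) {
  x <- RNifti::xform(img)
  R <- x[1:3, 1:3]
  sp <- sqrt(colSums(R^2))
  if (any(sp <= 0) || max(abs(R - diag(sp))) > 1e-4 * max(sp))
    stop("unsupported orientation in ", path,
         ": only axis-aligned (diagonal) affines are handled", call. = FALSE)
  list(spacing = sp, origin = x[1:3, 4])
}

#' Read and write volumes and labelmaps as NIfTI-1
#'
#' Orientation is handled through the affine only; the affine must be
#' axis-aligned (diagonal scaling plus translation). A write/read round trip
#' preserves values, spacing and origin to 1e-6.
#'
#' @param path a `.nii` or `.nii.gz` file
#' @return a [Volume-class] or [Labelmap-class]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3D scalar image, got ", length(dim(a)), "D: ", path,
         call. = FALSE)
  g <- .xformFromImage(img, path)
  Volume(array(as.numeric(a), dim(a)), spacing = g$spacing,
         origin = g$origin)
}

#' @rdname readVolume
#' @export
readLabelmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3D labelmap, got ", length(dim(a)), "D: ", path,
         call. = FALSE)
  g <- .xformFromImage(img, path)
  Labelmap(array(as.integer(round(a)), dim(a)), spacing = g$spacing,
           origin = g$origin)
}

#' @rdname readVolume
#' @param v a [Volume-class] or [Labelmap-class] to write
#' @export
writeVolume <- function(v, path) {
  img <- RNifti::asNifti(v@values)
  RNifti::pixdim(img) <- v@spacing  # qform stores scale through pixdim
  aff <- .affine(v@spacing, v@origin)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Sampling and warping -------------------------------------------------

#' Trilinear sampling of a volume at world coordinates
#'
#' Continuous and piecewise-trilinear in the query points; the volume is
#' conceptually zero-padded, so queries outside the bounds return 0 (air
#' outside the field of view).
#'
#' @param v a [Volume-class]
#' @param points M x 3 matrix of world coordinates (mm)
#' @return numeric vector of M interpolated values
#' @export
sampleTrilinear <- function(v, points) {
  points <- rbind(points)
  if (ncol(points) != 3L || any(!is.finite(points)))
    stop("points must be a finite M x 3 matrix", call. = FALSE)
  cpp_trilinear(as.vector(v@values), dim(v@values), v@spacing, v@origin,
                points)
}

#' Spatial gradient of the trilinear interpolant
#'
#' @inheritParams sampleTrilinear
#' @return M x 3 matrix of gradients (per mm)
#' @export
sampleTrilinearGradient <- function(v, points) {
  points <- rbind(points)
  cpp_trilinear_grad(as.vector(v@values), dim(v@values), v@spacing, v@origin,
                     points)
}

.checkLattice <- function(v, field) {
  fd <- if (is(field, "PolyrigidField")) field@weights@dim else dim(field@disp)[1:3]
  fs <- spacing(if (is(field, "PolyrigidField")) field@weights else field)
  fo <- origin(if (is(field, "PolyrigidField")) field@weights else field)
  if (!all(dim(v@values) == fd) || max(abs(v@spacing - fs)) > 1e-9 ||
      max(abs(v@origin - fo)) > 1e-9)
    stop("deformation field is not defined on the volume's lattice",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname warpVolume
setMethod("warpVolume", signature(v = "Volume", field = "PolyrigidField"),
  function(v, field) {
    .checkLattice(v, field)
    phi <- .fieldMapping(field)
    vals <- cpp_trilinear(as.vector(v@values), dim(v@values), v@spacing,
                          v@origin, phi)
    Volume(array(vals, dim(v@values)), v@spacing, v@origin)
  })

#' @rdname warpVolume
setMethod("warpVolume", signature(v = "Volume", field = "DenseField"),
  function(v, field) {
    .checkLattice(v, field)
    phi <- latticeWorld(v) + matrix(field@disp, ncol = 3)
    vals <- cpp_trilinear(as.vector(v@values), dim(v@values), v@spacing,
                          v@origin, phi)
    Volume(array(vals, dim(v@values)), v@spacing, v@origin)
  })

#' @rdname warpLabelmap
setMethod("warpLabelmap", signature(lm = "Labelmap", field = "PolyrigidField"),
  function(lm, field) {
    .checkLattice(lm, field)
    phi <- .fieldMapping(field)
    vals <- cpp_nearest(as.vector(lm@values), dim(lm@values), lm@spacing,
                        lm@origin, phi)
    Labelmap(array(vals, dim(lm@values)), lm@spacing, lm@origin)
  })

#' @rdname warpLabelmap
setMethod("warpLabelmap", signature(lm = "Labelmap", field = "DenseField"),
  function(lm, field) {
    .checkLattice(lm, field)
    phi <- latticeWorld(lm) + matrix(field@disp, ncol = 3)
    vals <- cpp_nearest(as.vector(lm@values), dim(lm@values), lm@spacing,
                        lm@origin, phi)
    Labelmap(array(vals, dim(lm@values)), lm@spacing, lm@origin)
  })

# ---- Morphology -----------------------------------------------------------

#' Erode every structure of a labelmap by a ball of physical radius
#'
#' A voxel is kept when its Euclidean distance to the structure's complement
#' exceeds the radius, which with the voxel-centre metric makes a radius of 0
#' the identity. A structure that vanishes entirely is reported via a
#' message.
#'
#' @param lm a [Labelmap-class]
#' @param radiusMm erosion radius in mm (>= 0)
#' @return the eroded [Labelmap-class]
#' @export
erodeLabelmap <- function(lm, radiusMm) {
  if (!is.finite(radiusMm) || radiusMm < 0)
    stop("erosion radius must be >= 0", call. = FALSE)
  d <- dim(lm@values)
  out <- array(0L, d)
  for (id in structureIds(lm)) {
    comp <- as.vector(lm@values != id)
    dist <- cpp_edt(comp, d, lm@spacing)
    keep <- array(!comp & dist > radiusMm, d)
    if (!any(keep))
      message("structure ", id, " vanished at erosion radius ", radiusMm,
              " mm")
    out[keep] <- id
  }
  Labelmap(out, lm@spacing, lm@origin)
}
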