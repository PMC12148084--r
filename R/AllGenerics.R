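#' @include AllClasses.R
NULL

#' Voxel spacing of a gridded object
#' @param x a Volume, Labelmap, WeightField or DenseField
#' @return numeric(3), spacing in mm
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' World origin of a gridded object
#' @param x a Volume, Labelmap, WeightField or DenseField
#' @return numeric(3), world position of voxel (0,0,0) in mm
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Underlying data array
#' @param x a Volume or Labelmap
#' @return the 3D array of values or labels
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel-to-world affine
#' @param x a Volume or Labelmap
#' @return 4x4 affine mapping 0-based voxel indices to world mm
#' @export
setGeneric("voxelToWorld", function(x) standardGeneric("voxelToWorld"))

#' Resample a volume through a deformation field
#'
#' The output voxel at lattice position `x` holds the trilinear sample of the
#' input at the mapped position `Phi(x)`; an identity field reproduces the
#' input exactly at voxel centres.
#'
#' @param v a [Volume-class]
#' @param field a [PolyrigidField-class] or [DenseField-class] on the same
#'   lattice as `v`
#' @return a warped [Volume-class]
#' @export
setGeneric("warpVolume", function(v, field) standardGeneric("warpVolume"))

#' Resample a labelmap through a deformation field (nearest neighbour)
#' @param lm a [Labelmap-class]
#' @param field a [PolyrigidField-class] or [DenseField-class]
#' @return a warped [Labelmap-class]
#' @export
setGeneric("warpLabelmap", function(lm, field) standardGeneric("warpLabelmap"))

#' Dense mapping grid of a deformation field
#'
#' Evaluates the mapping `Phi` at every voxel centre of the field's lattice.
#'
#' @param field a [PolyrigidField-class] or [DenseField-class]
#' @return a 4D array (nx, ny, nz, 3) of mapped world positions in mm
#' @export
setGeneric("mappingGrid", function(field) standardGeneric("mappingGrid"))

#' Dense displacement of a deformation field
#' @param field a [PolyrigidField-class] or [DenseField-class]
#' @return a [DenseField-class] with displacements `Phi(x) - x`
#' @export
setGeneric("displacementField",
           function(field) standardGeneric("displacementField"))

setMethod("spacing", "Volume", function(x) x@spacing)
setMethod("spacing", "Labelmap", function(x) x@spacing)
setMethod("spacing", "WeightField", function(x) x@spacing)
setMethod("spacing", "DenseField", function(x) x@spacing)
setMethod("origin", "Volume", function(x) x@origin)
setMethod("origin", "Labelmap", function(x) x@origin)
setMethod("origin", "WeightField", function(x) x@origin)
setMethod("origin", "DenseField", function(x) x@origin)
setMethod("voxelData", "Volume", function(x) x@values)
setMethod("voxelData", "Labelmap", function(x) x@values)

#' @export
setMethod("dim", "Volume", function(x) dim(x@values))
#' @export
setMethod("dim", "Labelmap", function(x) dim(x@values))

.affine <- function(spacing, origin) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}
setMethod("voxelToWorld", "Volume", function(x) .affine(x@spacing, x@origin))
setMethod("voxelToWorld", "Labelmap", function(x) .affine(x@spacing, x@origin))

setMethod("show", "Volume", function(object) {
  d <- dim(object)
  cat(sprintf("Volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, LAC range [%.4g, %.4g] /mm\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "Labelmap", function(object) {
  ids <- sort(setdiff(unique(as.vector(object@values)), 0L))
  d <- dim(object)
  cat(sprintf("Labelmap: %d x %d x %d voxels, %d structure(s): %s\n",
              d[1], d[2], d[3], length(ids), paste(ids, collapse = ", ")))
})

setMethod("show", "Camera", function(object) {
  S <- sourcePosition(object)
  cat(sprintf("Camera: %d x %d px detector, pixel spacing (%g, %g) mm\n",
              object@detectorShape[1], object@detectorShape[2],
              object@pixelSpacing[1], object@pixelSpacing[2]))
  cat(sprintf("  focal length %g mm, source at (%.2f, %.2f, %.2f) mm\n",
              focalLength(object), S[1], S[2], S[3]))
})

setMethod("show", "PolyrigidField", function(object) {
  cat(sprintf("PolyrigidField: %d rigid structure(s) on a %s lattice (%s weights)\n",
              nrow(object@twists),
              paste(object@weights@dim, collapse = " x "),
              object@weights@mode))
})

setMethod("show", "GroundTruthCase", function(object) {
  cat(sprintf("GroundTruthCase: %d view(s), %d structure(s), seed %d\n",
              length(object@cameras), nrow(object@gtTwists), object@seed))
})
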