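#' @include volume.R
NULL

#' Construct a Camera
#'
#' Either supply the intrinsic matrix directly, or give the focal length,
#' pixel spacing and principal point from which the standard construction
#' `K = [[f/sx, 0, cx], [0, f/sy, cy], [0, 0, 1]]` is assembled.
#'
#' @param extrinsic 4x4 rigid world-to-camera matrix
#' @param detectorShape integer(2), detector pixels along x and y
#' @param pixelSpacing numeric(2), detector pixel spacing (mm)
#' @param focalLengthMm source-to-detector focal length (mm)
#' @param principalPoint principal point in 0-based pixels; defaults to the
#'   detector centre
#' @param intrinsic optional 3x3 intrinsic matrix overriding the above
#' @return a [Camera-class]
#' @export
Camera <- function(extrinsic, detectorShape, pixelSpacing, focalLengthMm,
                   principalPoint = (detectorShape - 1) / 2,
                   intrinsic = NULL) {
  detectorShape <- as.integer(detectorShape)
  pixelSpacing <- as.numeric(pixelSpacing)
  if (is.null(intrinsic)) {
    intrinsic <- matrix(c(focalLengthMm / pixelSpacing[1], 0, 0,
                          0, focalLengthMm / pixelSpacing[2], 0,
                          principalPoint[1], principalPoint[2], 1), 3, 3)
  }
  new("Camera", intrinsic = intrinsic, extrinsic = extrinsic,
      detectorShape = detectorShape, pixelSpacing = pixelSpacing)
}

#' Focal length derived from the intrinsic matrix
#' @param c a [Camera-class]
#' @return focal length in mm
#' @export
focalLength <- function(c) c@intrinsic[1, 1] * c@pixelSpacing[1]

#' X-ray source position in world coordinates
#'
#' Returns `S = -R^T t`, the point satisfying `R S + t = 0`.
#'
#' @param c a [Camera-class]
#' @return numeric(3), source position in mm
#' @export
sourcePosition <- function(c) {
  R <- c@extrinsic[1:3, 1:3]
  as.vector(-crossprod(R, c@extrinsic[1:3, 4]))
}

#' Map detector pixels to world coordinates
#'
#' For a pixel `p` the detector point lies on the plane at distance `f` from
#' the source along the optical axis; projecting it back through the camera
#' recovers `p`.
#'
#' @param c a [Camera-class]
#' @param p M x 2 matrix of 0-based pixel coordinates
#' @return M x 3 matrix of world points (mm)
#' @export
pixelToWorld <- function(c, p) {
  p <- rbind(p)
  K <- c@intrinsic
  if (abs(K[1, 1] * K[2, 2]) < 1e-12)
    stop("singular projection geometry", call. = FALSE)
  f <- focalLength(c)
  xc <- cbind((p[, 1] - K[1, 3]) * c@pixelSpacing[1],
              (p[, 2] - K[2, 3]) * c@pixelSpacing[2],
              f)
  R <- c@extrinsic[1:3, 1:3]
  S <- sourcePosition(c)
  sweep(xc %*% R, 2, S, "+")
}

#' Project world points to detector pixels
#'
#' @param c a [Camera-class]
#' @param x M x 3 matrix of world points (mm)
#' @return M x 2 matrix of 0-based pixel coordinates
#' @export
projectWorld <- function(c, x) {
  x <- rbind(x)
  R <- c@extrinsic[1:3, 1:3]
  t <- c@extrinsic[1:3, 4]
  xc <- sweep(x %*% t(R), 2, t, "+")
  K <- c@intrinsic
  cbind(K[1, 1] * xc[, 1] / xc[, 3] + K[1, 3],
        K[2, 2] * xc[, 2] / xc[, 3] + K[2, 3])
}

# Source and per-pixel detector target points for every detector pixel,
# column-major pixel order matching the image matrix layout.
.detectorRays <- function(c) {
  nx <- c@detectorShape[1]
  ny <- c@detectorShape[2]
  px <- cbind(rep(seq_len(nx) - 1, times = ny),
              rep(seq_len(ny) - 1, each = nx))
  list(src = matrix(sourcePosition(c), 1, 3), dst = pixelToWorld(c, px))
}

#' Replace a camera's extrinsic matrix
#' @param c a [Camera-class]
#' @param extrinsic new 4x4 rigid world-to-camera matrix
#' @return the updated [Camera-class]
#' @export
setExtrinsic <- function(c, extrinsic) {
  new("Camera", intrinsic = c@intrinsic, extrinsic = extrinsic,
      detectorShape = c@detectorShape, pixelSpacing = c@pixelSpacing)
}

# ---- Geometry JSON --------------------------------------------------------

#' Read and write per-view camera geometry as JSON
#'
#' Each view is an object with `focal_length_mm`, `pixel_spacing_mm` (2),
#' `principal_point_px` (2), `detector_shape_px` (2) and `extrinsic` (16
#' row-major floats or a length-6 twist).
#'
#' @param cameras list of [Camera-class]
#' @param path JSON file path
#' @return `readGeometry` returns a list of [Camera-class]
#' @export
writeGeometry <- function(cameras, path) {
  views <- lapply(cameras, function(c) {
    list(focal_length_mm = focalLength(c),
         pixel_spacing_mm = c@pixelSpacing,
         principal_point_px = c(c@intrinsic[1, 3], c@intrinsic[2, 3]),
         detector_shape_px = c@detectorShape,
         extrinsic = as.vector(t(c@extrinsic)))
  })
  jsonlite::write_json(list(views = views), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  views <- obj$views
  idx <- if (is.data.frame(views)) seq_len(nrow(views)) else seq_along(views)
  lapply(idx, function(i) {
    v <- if (is.data.frame(views)) lapply(views, function(col) {
      if (is.list(col)) col[[i]] else col[i]
    }) else views[[i]]
    ext <- as.numeric(unlist(v$extrinsic))
    T <- if (length(ext) == 6) expSE3(ext) else matrix(ext, 4, 4, byrow = TRUE)
    Camera(extrinsic = T,
           detectorShape = as.integer(unlist(v$detector_shape_px)),
           pixelSpacing = as.numeric(unlist(v$pixel_spacing_mm)),
           focalLengthMm = as.numeric(v$focal_length_mm),
           principalPoint = as.numeric(unlist(v$principal_point_px)))
  })
}

# ---- Projection image I/O -------------------------------------------------

#' Read and write 2D projection images
#'
#' Images are negative log-intensities (line integrals). Supported formats:
#' 2D NIfTI (float, lossless), 32-bit float TIFF, and 16-bit PNG/TIFF with a
#' scale factor recorded in a JSON sidecar.
#'
#' @param img numeric matrix of negative log-intensities
#' @param path output path (`.nii`, `.nii.gz`, `.tif`/`.tiff` or `.png`)
#' @param camera optional [Camera-class] recorded in the sidecar JSON
#' @return `readProjection` returns the image matrix
#' @export
writeProjection <- function(img, path, camera = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else if (grepl("\\.tiff?$", path)) {
    scale <- max(img, 1e-12)  # raster formats store [0, 1]
    tiff::writeTIFF(t(img)[ncol(img):1, , drop = FALSE] / scale, path,
                    bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.png$", path)) {
    scale <- max(img, 1e-12)
    png::writePNG(t(img)[ncol(img):1, , drop = FALSE] / scale, path)
    jsonlite::write_json(list(scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported image format: ", path, call. = FALSE)
  if (!is.null(camera)) writeGeometry(list(camera), paste0(path, ".geom.json"))
  invisible(path)
}

#' @rdname writeProjection
#' @export
readProjection <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) != 2L) stop("expected a 2D image: ", path, call. = FALSE)
    matrix(as.numeric(a), nrow(a))
  } else if (grepl("\\.tiff?$", path)) {
    m <- tiff::readTIFF(path)
    img <- t(m[nrow(m):1, , drop = FALSE])
    side <- paste0(path, ".json")
    if (file.exists(side))
      img <- img * jsonlite::read_json(side)$scale
    img
  } else if (grepl("\\.png$", path)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    img <- t(m[nrow(m):1, , drop = FALSE])
    side <- paste0(path, ".json")
    if (file.exists(side))
      img <- img * jsonlite::read_json(side)$scale
    img
  } else stop("unsupported image format: ", path, call. = FALSE)
}
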