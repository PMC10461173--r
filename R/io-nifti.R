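#' ImageVolume: a scalar 3D image with physical geometry
#'
#' Same geometry model as \linkS4class{LabelVolume} but with real-valued
#' voxels; used for anatomical (CT) images that drive registration.
#'
#' @slot voxels 3D numeric array.
#' @slot spacing,origin,direction As in \linkS4class{LabelVolume}.
#' @export
setClass("ImageVolume", representation(
  voxels = "array",
  spacing = "numeric",
  origin = "numeric",
  direction = "matrix"
))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  TRUE
})

#' @rdname ImageVolume-class
#' @param voxels 3D numeric array.
#' @param spacing,origin,direction Grid geometry (see
#'   \linkS4class{LabelVolume}).
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' @rdname ImageVolume-class
#' @param object An \linkS4class{ImageVolume}.
#' @export
setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

# RNifti arrays carry the niftiImage class; strip to a plain array.
plainArray <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

niftiGeometry <- function(img) {
  x <- RNifti::xform(img)
  A <- x[1:3, 1:3]
  sp <- sqrt(colSums(A^2))
  if (any(!is.finite(sp)) || any(sp <= 0))
    formatError("NIfTI file has missing or degenerate geometry")
  list(spacing = sp, origin = x[1:3, 4], direction = A %*% diag(1 / sp))
}

asNiftiWithGeometry <- function(arr, spacing, origin, direction) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd > 3L) c(spacing, rep(1, nd - 3L)) else
    spacing
  m <- diag(4)
  m[1:3, 1:3] <- direction %*% diag(spacing)
  m[1:3, 4] <- origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  img
}

#' Read and write NIfTI label volumes
#'
#' Voxel values and geometry (spacing, origin, orientation) round trip
#' exactly. Files whose voxel values deviate from integers by more than
#' 1e-6 are rejected with a format error.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param vol A \linkS4class{LabelVolume}.
#' @return \code{readLabelVolume} returns a \linkS4class{LabelVolume};
#'   \code{writeLabelVolume} returns \code{path} invisibly.
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- plainArray(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    formatError("'%s' is not a 3D volume", path)
  g <- niftiGeometry(img)
  labelVolume(a, spacing = g$spacing, origin = g$origin,
              direction = g$direction)
}

#' @rdname readLabelVolume
#' @export
writeLabelVolume <- function(vol, path) {
  img <- asNiftiWithGeometry(vol@voxels, vol@spacing, vol@origin,
                             vol@direction)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Read and write scalar (e.g. CT) NIfTI volumes
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param vol An \linkS4class{ImageVolume}.
#' @return \code{readImageVolume} returns an \linkS4class{ImageVolume}.
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- plainArray(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    formatError("'%s' is not a 3D volume", path)
  g <- niftiGeometry(img)
  imageVolume(a, spacing = g$spacing, origin = g$origin,
              direction = g$direction)
}

#' @rdname readImageVolume
#' @export
writeImageVolume <- function(vol, path) {
  img <- asNiftiWithGeometry(vol@voxels, vol@spacing, vol@origin,
                             vol@direction)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write displacement fields as vector NIfTI
#'
#' The field is a 4D NIfTI (x, y, z, component) in mm. Convention: the
#' displacement is defined on the fixed grid and, added to a fixed-space
#' point, yields the corresponding moving-space sampling point (see
#' \linkS4class{SpatialTransform}).
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param transform A \linkS4class{DisplacementFieldTransform}.
#' @return \code{readDisplacementField} returns a
#'   \linkS4class{DisplacementFieldTransform}.
#' @export
readDisplacementField <- function(path) {
  img <- RNifti::readNifti(path)
  a <- plainArray(img)
  if (length(dim(a)) == 5L && dim(a)[4] == 1L)
    a <- array(a, dim(a)[c(1, 2, 3, 5)])  # NIfTI vector intent stores on dim 5
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    formatError("'%s' is not a 3-component vector volume", path)
  g <- niftiGeometry(img)
  new("DisplacementFieldTransform", field = a, fieldSpacing = g$spacing,
      fieldOrigin = g$origin, fieldDirection = g$direction)
}

#' @rdname readDisplacementField
#' @export
writeDisplacementField <- function(transform, path) {
  img <- asNiftiWithGeometry(transform@field, transform@fieldSpacing,
                             transform@fieldOrigin,
                             transform@fieldDirection)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
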