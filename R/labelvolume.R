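#' Construct a LabelVolume
#'
#' @param voxels 3D array of non-negative integers (value 0 = background) or
#'   logicals (for binary masks).
#' @param spacing Voxel spacing in mm (length 3, all > 0).
#' @param origin Physical position of voxel (0,0,0) in mm.
#' @param direction 3x3 direction-cosine matrix.
#' @return A \linkS4class{LabelVolume}.
#' @examples
#' v <- labelVolume(array(0L, c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' spacing(v)
#' @export
labelVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (is.logical(voxels)) {
    voxels <- array(as.integer(voxels), dim = dim(voxels))
  } else if (is.double(voxels)) {
    r <- round(voxels)
    if (max(abs(voxels - r)) > 1e-6)
      formatError("voxel values are not integers (max deviation %.3g)",
                  max(abs(voxels - r)))
    voxels <- array(as.integer(r), dim = dim(voxels))
  }
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' @rdname LabelVolume-class
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)

#' @rdname LabelVolume-class
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)

#' @rdname LabelVolume-class
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)

#' @rdname LabelVolume-class
#' @export
setMethod("direction", "LabelVolume", function(x) x@direction)

#' @rdname LabelVolume-class
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))

#' @rdname LabelVolume-class
#' @export
setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  labs <- labelValues(object)
  cat(sprintf("LabelVolume %dx%dx%d, spacing %s mm, %d lesion label%s\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              length(labs), if (length(labs) == 1L) "" else "s"))
})

#' Distinct positive labels present in a volume
#'
#' @param vol A \linkS4class{LabelVolume}.
#' @return Sorted integer vector of lesion indices.
#' @export
labelValues <- function(vol) {
  u <- sort(unique(as.vector(vol@voxels)))
  u[u > 0L]
}

#' Physical volume of one voxel in cm^3
#'
#' @param vol A \linkS4class{LabelVolume} or \linkS4class{LesionSet}.
#' @return Voxel volume in cm^3 (product of spacings / 1000).
#' @export
voxelVolumeCm3 <- function(vol) prod(vol@spacing) / 1000
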