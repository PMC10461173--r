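#' @import methods
NULL

#' Map physical points through a spatial transform
#'
#' Transforms map points expressed in the fixed image's physical space to the
#' corresponding sampling locations in the moving image's physical space (the
#' standard resampling convention, as used by ITK/elastix).
#'
#' @param transform A \linkS4class{SpatialTransform}.
#' @param points Numeric matrix with one row per point and three columns (mm).
#' @return Numeric matrix of mapped points, same shape as \code{points}.
#' @export
setGeneric("transformPoints", function(transform, points)
  standardGeneric("transformPoints"))

#' @rdname LabelVolume-class
#' @param x,object A \linkS4class{LabelVolume}.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname LabelVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname LabelVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname LabelVolume-class
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname MatchGraph-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname MatchGraph-class
#' @export
setGeneric("nodes1", function(x) standardGeneric("nodes1"))

#' @rdname MatchGraph-class
#' @export
setGeneric("nodes2", function(x) standardGeneric("nodes2"))
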