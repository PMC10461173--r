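#' Sentinel node labels
#'
#' Reserved tokens used in match graphs for lesions without a counterpart:
#' \code{NEW_NODE} ("NEW") sits on the scan-1 side and collects lesions that
#' are new on scan 2; \code{DISAPPEARED_NODE} ("DISAPPEARED") sits on the
#' scan-2 side and collects lesions that disappeared after scan 1. They are
#' tokens, never integer 0: the zero convention exists only in the
#' reader-workbook CSV dialect (see \code{\link{readMatchTable}}).
#'
#' @export
NEW_NODE <- "NEW"

#' @rdname NEW_NODE
#' @export
DISAPPEARED_NODE <- "DISAPPEARED"

#' LabelVolume: a 3D integer image with physical geometry
#'
#' A 3D voxel grid in which value 0 is background and each positive integer
#' identifies one lesion. Geometry follows the NIfTI convention: a voxel with
#' zero-based index \eqn{i} sits at physical position
#' \eqn{origin + direction \cdot diag(spacing) \cdot i} (mm).
#'
#' @slot voxels 3D array of non-negative integers (or logicals for masks).
#' @slot spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @slot origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @slot direction 3x3 direction-cosine matrix.
#'
#' @seealso \code{\link{labelVolume}}, \code{\link{readLabelVolume}}
#' @export
setClass("LabelVolume", representation(
  voxels = "array",
  spacing = "numeric",
  origin = "numeric",
  direction = "matrix"
))

setValidity("LabelVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3D array")
  if (!(is.integer(v) || is.logical(v) || is.numeric(v)))
    return("voxels must be integer, numeric or logical")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (mm)")
  if (!all(dim(object@direction) == c(3L, 3L)))
    return("direction must be a 3x3 matrix")
  rng <- suppressWarnings(range(v))
  if (is.finite(rng[1]) && rng[1] < 0)
    return("voxel values must be >= 0 (0 = background)")
  TRUE
})

#' MatchGraph: bipartite lesion correspondences between two scans
#'
#' Nodes are lesion indices on scan 1 (\code{n1}) and scan 2 (\code{n2}),
#' augmented with one sentinel per side (\code{NEW} on the scan-1 side,
#' \code{DISAPPEARED} on the scan-2 side). An edge asserts that two labelled
#' lesions are the same physical lesion; a sentinel edge asserts that a
#' lesion has no counterpart. Edges are stored canonically as a two-column
#' character matrix (scan-1 element, scan-2 element), duplicate-free and
#' sorted; graph equality is set equality of canonical edges.
#'
#' @slot n1 Sorted integer vector of scan-1 lesion indices.
#' @slot n2 Sorted integer vector of scan-2 lesion indices.
#' @slot edges Two-column character matrix; entries are decimal integers or
#'   the sentinel tokens.
#'
#' @seealso \code{\link{buildGraph}}, \code{\link{validateGraph}},
#'   \code{\link{compareGraphs}}
#' @export
setClass("MatchGraph", representation(
  n1 = "integer",
  n2 = "integer",
  edges = "matrix"
))

setValidity("MatchGraph", function(object) {
  if (anyDuplicated(object@n1) || anyDuplicated(object@n2))
    return("lesion indices must be unique within a scan")
  if (any(object@n1 < 1L) || any(object@n2 < 1L))
    return("lesion indices must be positive integers")
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  TRUE
})

#' MetricsReport: agreement metrics for an ordered pair of edge sets
#'
#' Precision, recall, F1 and the number of differences N_d (cardinality of
#' the symmetric difference) between two match graphs' edge sets. Sentinel
#' edges count as ordinary edges. When an edge set is empty the affected
#' ratio is reported as 1 and a flag is recorded.
#'
#' @slot precision,recall,f1 Fractions in [0, 1].
#' @slot nDifferences Non-negative integer.
#' @slot flags Character vector of conventions applied (e.g.
#'   \code{"empty_e_a"}).
#' @export
setClass("MetricsReport", representation(
  precision = "numeric",
  recall = "numeric",
  f1 = "numeric",
  nDifferences = "integer",
  flags = "character"
))

setValidity("MetricsReport", function(object) {
  for (s in c("precision", "recall", "f1")) {
    x <- slot(object, s)
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      return(sprintf("%s must be a single value in [0, 1]", s))
  }
  if (object@nDifferences < 0L)
    return("nDifferences must be non-negative")
  TRUE
})

#' Spatial transforms
#'
#' A \code{SpatialTransform} maps points from the fixed image's physical
#' space to sampling locations in the moving image's physical space (the
#' resampling convention; see \code{\link{transformPoints}}). Concrete kinds:
#' identity, rigid translation, B-spline free-form deformation, dense
#' displacement field, and composite.
#'
#' For \code{TranslationTransform}, \code{offset} is the shift applied to
#' the moving image's content to align it with the fixed image (so sampling
#' evaluates the moving image at \code{p - offset}).
#'
#' @slot offset Numeric length-3 translation in mm (moving onto fixed).
#' @aliases IdentityTransform-class TranslationTransform-class
#'   BSplineTransform-class DisplacementFieldTransform-class
#'   CompositeTransform-class
#' @export
setClass("SpatialTransform", representation("VIRTUAL"))

#' @rdname SpatialTransform-class
#' @export
setClass("IdentityTransform", contains = "SpatialTransform")

#' @rdname SpatialTransform-class
#' @export
setClass("TranslationTransform", contains = "SpatialTransform",
         representation(offset = "numeric"))

setValidity("TranslationTransform", function(object) {
  if (length(object@offset) != 3L || any(!is.finite(object@offset)))
    return("offset must be three finite values (mm)")
  TRUE
})

#' @rdname SpatialTransform-class
#' @slot gridOrigin Physical position (mm) of the first control point.
#' @slot gridSpacing Control-point spacing (mm), length 3.
#' @slot gridDim Number of control points per axis, length 3.
#' @slot coefficients Matrix (prod(gridDim) x 3) of control-point
#'   displacements in mm, added to the input point (cubic B-spline tensor
#'   interpolation).
#' @export
setClass("BSplineTransform", contains = "SpatialTransform",
         representation(gridOrigin = "numeric", gridSpacing = "numeric",
                        gridDim = "integer", coefficients = "matrix"))

setValidity("BSplineTransform", function(object) {
  if (length(object@gridDim) != 3L || any(object@gridDim < 4L))
    return("control grid needs at least 4 points per axis")
  if (nrow(object@coefficients) != prod(object@gridDim) ||
      ncol(object@coefficients) != 3L)
    return("coefficients must be prod(gridDim) x 3")
  TRUE
})

#' @rdname SpatialTransform-class
#' @slot field 4D array (x, y, z, 3): displacement in mm defined on the
#'   fixed grid; the mapped point is the input point plus the (trilinearly
#'   interpolated) displacement.
#' @slot fieldSpacing,fieldOrigin,fieldDirection Geometry of the field grid.
#' @export
setClass("DisplacementFieldTransform", contains = "SpatialTransform",
         representation(field = "array", fieldSpacing = "numeric",
                        fieldOrigin = "numeric", fieldDirection = "matrix"))

setValidity("DisplacementFieldTransform", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L || d[4] != 3L)
    return("field must be a 4D array with 3 components in the last dimension")
  if (length(object@fieldSpacing) != 3L || any(object@fieldSpacing <= 0))
    return("field spacing must be three positive values")
  TRUE
})

#' @rdname SpatialTransform-class
#' @slot transforms List of component transforms, applied to a point in
#'   declared order (first element first).
#' @export
setClass("CompositeTransform", contains = "SpatialTransform",
         representation(transforms = "list"))

setValidity("CompositeTransform", function(object) {
  if (!length(object@transforms) ||
      !all(vapply(object@transforms, is, logical(1), "SpatialTransform")))
    return("transforms must be a non-empty list of SpatialTransform objects")
  TRUE
})

#' LesionSet: per-scan lesion records on one voxel grid
#'
#' One record per labelled lesion: index, voxel count, physical volume
#' (cm^3, exactly voxel count x voxel volume / 1000), and the lesion's
#' binary mask stored as a cropped bounding box on the parent grid. After
#' \code{\link{dilateLesions}}, each record also carries a dilated mask.
#'
#' @slot indices Integer lesion indices (unique, positive).
#' @slot voxelCount Integer voxels per lesion.
#' @slot volumeCm3 Physical volumes in cm^3.
#' @slot masks List of cropped masks: \code{list(offset =} 1-based corner
#'   index, \code{mask =} logical 3D array\code{)}.
#' @slot dilated List of cropped dilated masks (or \code{NULL}s before
#'   dilation).
#' @slot dilationMm Radius used to populate \code{dilated} (NA before).
#' @slot dim,spacing,origin,direction Geometry of the parent grid.
#' @seealso \code{\link{lesionSet}}, \code{\link{filterByVolume}}
#' @export
setClass("LesionSet", representation(
  indices = "integer",
  voxelCount = "integer",
  volumeCm3 = "numeric",
  masks = "list",
  dilated = "list",
  dilationMm = "numeric",
  dim = "integer",
  spacing = "numeric",
  origin = "numeric",
  direction = "matrix"
))

setValidity("LesionSet", function(object) {
  n <- length(object@indices)
  if (anyDuplicated(object@indices) || any(object@indices < 1L))
    return("lesion indices must be unique positive integers")
  if (length(object@voxelCount) != n || length(object@volumeCm3) != n ||
      length(object@masks) != n || length(object@dilated) != n)
    return("record slots must all have one entry per lesion")
  vv <- prod(object@spacing) / 1000
  if (n && max(abs(object@volumeCm3 - object@voxelCount * vv)) > 1e-9)
    return("volumeCm3 must equal voxelCount x voxel volume / 1000")
  TRUE
})

#' MatchConfig: tunable parameters of the automated matcher
#'
#' @slot dilationMm Physical dilation radius in mm applied to every lesion
#'   before clustering and overlap computation (default 25, absorbing
#'   registration uncertainty).
#' @slot minVolumeCm3 Lesions must exceed this volume strictly to take part
#'   in matching (default 0.1 cm^3).
#' @slot connectivity Voxel connectivity for component labelling: 6, 18 or
#'   26 (default 26).
#' @slot regMode One of \code{"auto"}, \code{"field"}, \code{"translation"},
#'   \code{"identity"}.
#' @slot regGridSpacingMm B-spline control-point spacing in mm (default 50).
#' @slot regMetric Similarity metric for the deformable stage (\code{"msd"},
#'   mean squared difference).
#' @slot regIterations Optimiser iteration budget per resolution level.
#' @slot regLevels Number of multi-resolution levels.
#' @slot regSeed Seed reserved for any stochastic sampling in the
#'   registration stage (the default sampler is deterministic).
#' @seealso \code{\link{matchConfig}}, \code{\link{matchPipeline}}
#' @export
setClass("MatchConfig", representation(
  dilationMm = "numeric",
  minVolumeCm3 = "numeric",
  connectivity = "integer",
  regMode = "character",
  regGridSpacingMm = "numeric",
  regMetric = "character",
  regIterations = "integer",
  regLevels = "integer",
  regSeed = "integer"
))

setValidity("MatchConfig", function(object) {
  if (object@dilationMm < 0) return("dilationMm must be >= 0")
  if (object@minVolumeCm3 < 0) return("minVolumeCm3 must be >= 0")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  if (!object@regMode %in% c("auto", "field", "translation", "identity"))
    return("regMode must be auto, field, translation or identity")
  if (object@regGridSpacingMm <= 0) return("regGridSpacingMm must be > 0")
  TRUE
})

#' PhantomSpec: parameters of the synthetic longitudinal phantom
#'
#' Describes a pair of simulated scans: ellipsoidal lesions on scan 1, a
#' smooth band-limited sinusoidal deformation carrying them to scan 2, and
#' per-lesion appearance/disappearance/split/merge events. Identical specs
#' (same seed) generate bit-identical phantoms.
#'
#' @slot gridShape Integer length-3 voxel grid dimensions.
#' @slot spacingMm Numeric length-3 voxel spacing (mm).
#' @slot nLesions Number of lesions on scan 1.
#' @slot volumeRangeCm3 Min and max lesion volume (cm^3); volumes are drawn
#'   log-uniformly.
#' @slot pDisappear,pNew,pSplit,pMerge Per-lesion event probabilities
#'   (pDisappear + pSplit <= 1).
#' @slot deformationAmplitudeMm Maximum displacement magnitude (mm).
#' @slot deformationWavelengthMm Wavelength of the sinusoidal deformation
#'   (mm, > 0).
#' @slot minSeparationMm Minimum centre-to-centre distance between placed
#'   lesions (mm); merge pairs and split fragments are placed closer by
#'   design.
#' @slot seed Integer RNG seed.
#' @seealso \code{\link{phantomSpec}}, \code{\link{generatePhantomPair}}
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer",
  spacingMm = "numeric",
  nLesions = "integer",
  volumeRangeCm3 = "numeric",
  pDisappear = "numeric",
  pNew = "numeric",
  pSplit = "numeric",
  pMerge = "numeric",
  deformationAmplitudeMm = "numeric",
  deformationWavelengthMm = "numeric",
  minSeparationMm = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  p <- c(object@pDisappear, object@pNew, object@pSplit, object@pMerge)
  if (any(p < 0) || any(p > 1))
    return("event probabilities must be in [0, 1]")
  if (object@pDisappear + object@pSplit > 1)
    return("pDisappear + pSplit must be <= 1")
  if (object@deformationWavelengthMm <= 0)
    return("deformationWavelengthMm must be > 0")
  if (object@nLesions < 0L) return("nLesions must be >= 0")
  if (length(object@volumeRangeCm3) != 2L ||
      any(object@volumeRangeCm3 <= 0) ||
      diff(object@volumeRangeCm3) < 0)
    return("volumeRangeCm3 must be an increasing positive pair")
  TRUE
})
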