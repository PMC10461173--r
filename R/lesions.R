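cropMask <- function(which3, d) {
  lo <- apply(which3, 2, min)
  hi <- apply(which3, 2, max)
  arr <- array(FALSE, hi - lo + 1L)
  arr[cbind(which3[, 1] - lo[1] + 1L, which3[, 2] - lo[2] + 1L,
            which3[, 3] - lo[3] + 1L)] <- TRUE
  list(offset = lo, mask = arr)
}

#' Extract per-lesion records from a label volume
#'
#' Builds a \linkS4class{LesionSet}: one record per distinct positive label
#' with its voxel count, physical volume (cm^3) and cropped binary mask.
#' Indices are taken from the label values and are not relabelled.
#'
#' @param vol A \linkS4class{LabelVolume}.
#' @return A \linkS4class{LesionSet}.
#' @export
lesionSet <- function(vol) {
  d <- dim(vol@voxels)
  fg <- which(vol@voxels > 0L)
  labs <- vol@voxels[fg]
  idx <- sort(unique(labs))
  ijk <- arrayInd(fg, d)
  masks <- lapply(idx, function(l) cropMask(ijk[labs == l, , drop = FALSE],
                                            d))
  counts <- vapply(idx, function(l) sum(labs == l), integer(1))
  new("LesionSet", indices = as.integer(idx), voxelCount = counts,
      volumeCm3 = counts * prod(vol@spacing) / 1000,
      masks = masks, dilated = rep(list(NULL), length(idx)),
      dilationMm = NA_real_, dim = as.integer(d), spacing = vol@spacing,
      origin = vol@origin, direction = vol@direction)
}

#' @rdname LesionSet-class
#' @param x,object A \linkS4class{LesionSet}.
#' @export
setMethod("length", "LesionSet", function(x) length(x@indices))

#' @rdname LesionSet-class
#' @param i Indices (positions) to keep.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "LesionSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, indices = x@indices[i], voxelCount = x@voxelCount[i],
             volumeCm3 = x@volumeCm3[i], masks = x@masks[i],
             dilated = x@dilated[i])
})

#' @rdname LesionSet-class
#' @export
setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet: %d lesion%s on a %s grid", length(object@indices),
              if (length(object@indices) == 1L) "" else "s",
              paste(object@dim, collapse = "x")))
  if (length(object@indices))
    cat(sprintf(", volumes %.3g-%.3g cm^3", min(object@volumeCm3),
                max(object@volumeCm3)))
  if (!is.na(object@dilationMm))
    cat(sprintf(", dilated by %g mm", object@dilationMm))
  cat("\n")
})

#' Lesion volumes
#'
#' @param lesions A \linkS4class{LesionSet}.
#' @return Named numeric vector of volumes in cm^3 (names = lesion
#'   indices).
#' @export
lesionVolumes <- function(lesions)
  stats::setNames(lesions@volumeCm3, lesions@indices)

#' Drop lesions at or below a volume threshold
#'
#' Retains exactly the lesions whose physical volume strictly exceeds
#' \code{minVolumeCm3}; indices are unchanged (no relabelling). The
#' analysis default of 0.1 cm^3 reflects the smallest lesions that can be
#' contoured and matched reliably; a 0.1 cm^3 lesion is removed (strict
#' inequality).
#'
#' @param lesions A \linkS4class{LesionSet}.
#' @param minVolumeCm3 Volume threshold in cm^3 (default 0.1).
#' @return A \linkS4class{LesionSet} with the surviving lesions.
#' @export
filterByVolume <- function(lesions, minVolumeCm3 = 0.1) {
  lesions[lesions@volumeCm3 > minVolumeCm3]
}
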