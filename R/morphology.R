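# Ball structuring element honouring anisotropic spacing: a voxel offset
# (dx, dy, dz) belongs to the ball iff its physical length is <= radius.
ballKernel <- function(spacing, radiusMm) {
  r <- pmax(0L, as.integer(floor(radiusMm / spacing + 1e-9)))
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  k <- array(0, 2L * r + 1L)
  inside <- d2 <= radiusMm^2 + 1e-9
  k[cbind(g[inside, 1] + r[1] + 1L, g[inside, 2] + r[2] + 1L,
          g[inside, 3] + r[3] + 1L)] <- 1
  k
}

# Dilate one cropped mask by the kernel, clipping to the parent grid.
dilateCropped <- function(cm, kernel, gridDim) {
  dk <- dim(kernel)
  r <- (dk - 1L) %/% 2L
  conv <- fftConvolve3(cm$mask * 1, kernel)
  dil <- conv > 0.5
  lo <- cm$offset - r
  # clip to [1, gridDim]
  cutLo <- pmax(1L - lo, 0L)
  hi <- lo + dim(dil) - 1L
  cutHi <- pmax(hi - gridDim, 0L)
  dd <- dim(dil)
  dil <- dil[(1L + cutLo[1]):(dd[1] - cutHi[1]),
             (1L + cutLo[2]):(dd[2] - cutHi[2]),
             (1L + cutLo[3]):(dd[3] - cutHi[3]), drop = FALSE]
  list(offset = lo + cutLo, mask = dil)
}

#' Dilate every lesion by a physical radius
#'
#' Populates each lesion's dilated mask with the morphological dilation of
#' its mask by a Euclidean ball of \code{radiusMm} millimetres: a voxel
#' belongs to the dilated mask iff its centre lies within \code{radiusMm}
#' of some lesion-voxel centre, with anisotropic spacing respected. The
#' dilation absorbs residual registration error before overlaps are
#' computed (default 25 mm in \code{\link{matchConfig}}).
#'
#' @param lesions A \linkS4class{LesionSet}.
#' @param radiusMm Dilation radius in mm (>= 0; 0 leaves masks unchanged).
#' @return The \linkS4class{LesionSet} with \code{dilated} populated.
#' @export
dilateLesions <- function(lesions, radiusMm = 25) {
  if (radiusMm < 0)
    validationError("dilation radius must be >= 0")
  if (radiusMm == 0) {
    lesions@dilated <- lesions@masks
    lesions@dilationMm <- 0
    return(lesions)
  }
  kernel <- ballKernel(lesions@spacing, radiusMm)
  lesions@dilated <- lapply(lesions@masks, dilateCropped, kernel = kernel,
                            gridDim = lesions@dim)
  lesions@dilationMm <- radiusMm
  lesions
}

# Voxel overlap count of two cropped masks (0 if bounding boxes disjoint).
croppedOverlapCount <- function(a, b) {
  lo <- pmax(a$offset, b$offset)
  hi <- pmin(a$offset + dim(a$mask) - 1L, b$offset + dim(b$mask) - 1L)
  if (any(hi < lo)) return(0L)
  sa <- a$mask[(lo[1] - a$offset[1] + 1L):(hi[1] - a$offset[1] + 1L),
               (lo[2] - a$offset[2] + 1L):(hi[2] - a$offset[2] + 1L),
               (lo[3] - a$offset[3] + 1L):(hi[3] - a$offset[3] + 1L),
               drop = FALSE]
  sb <- b$mask[(lo[1] - b$offset[1] + 1L):(hi[1] - b$offset[1] + 1L),
               (lo[2] - b$offset[2] + 1L):(hi[2] - b$offset[2] + 1L),
               (lo[3] - b$offset[3] + 1L):(hi[3] - b$offset[3] + 1L),
               drop = FALSE]
  sum(sa & sb)
}

# Union of cropped masks -> one cropped mask.
unionCropped <- function(masks) {
  lo <- do.call(pmin, lapply(masks, `[[`, "offset"))
  hi <- do.call(pmax, lapply(masks, function(m) m$offset + dim(m$mask) - 1L))
  arr <- array(FALSE, hi - lo + 1L)
  for (m in masks) {
    o <- m$offset - lo
    dm <- dim(m$mask)
    sub <- arr[(o[1] + 1L):(o[1] + dm[1]), (o[2] + 1L):(o[2] + dm[2]),
               (o[3] + 1L):(o[3] + dm[3]), drop = FALSE]
    arr[(o[1] + 1L):(o[1] + dm[1]), (o[2] + 1L):(o[2] + dm[2]),
        (o[3] + 1L):(o[3] + dm[3])] <- sub | m$mask
  }
  list(offset = lo, mask = arr)
}
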