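#' Transform constructors
#'
#' \code{identityTransform()} maps every point to itself.
#' \code{translationTransform(offset)} records the rigid shift (mm) that
#' aligns the moving image's content onto the fixed image; sampling
#' evaluates the moving image at \code{p - offset}.
#' \code{compositeTransform(...)} chains transforms, applied to a point in
#' the declared order.
#' \code{displacementFieldTransform(field, spacing, origin, direction)}
#' wraps a dense displacement field (4D array, mm) defined on the fixed
#' grid.
#'
#' @param offset Numeric length-3 (mm).
#' @param ... SpatialTransform objects (or a single list of them).
#' @param field 4D array (x, y, z, 3), displacements in mm.
#' @param spacing,origin,direction Geometry of the field grid.
#' @return A \linkS4class{SpatialTransform}.
#' @export
identityTransform <- function() new("IdentityTransform")

#' @rdname identityTransform
#' @export
translationTransform <- function(offset)
  new("TranslationTransform", offset = as.numeric(offset))

#' @rdname identityTransform
#' @export
compositeTransform <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !is(ts[[1]], "SpatialTransform"))
    ts <- ts[[1]]
  new("CompositeTransform", transforms = ts)
}

#' @rdname identityTransform
#' @export
displacementFieldTransform <- function(field, spacing = c(1, 1, 1),
                                       origin = c(0, 0, 0),
                                       direction = diag(3)) {
  new("DisplacementFieldTransform", field = field,
      fieldSpacing = as.numeric(spacing), fieldOrigin = as.numeric(origin),
      fieldDirection = direction)
}

#' Reported translation of a rigid alignment
#'
#' The vector (mm) by which the moving image's content is shifted to land
#' on the fixed image.
#'
#' @param transform A \linkS4class{TranslationTransform}.
#' @return Numeric length-3.
#' @export
translation <- function(transform) {
  stopifnot(is(transform, "TranslationTransform"))
  transform@offset
}

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "IdentityTransform",
          function(transform, points) points)

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "TranslationTransform",
          function(transform, points)
            sweep(points, 2L, transform@offset, "-"))

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "CompositeTransform",
          function(transform, points) {
            for (t in transform@transforms)
              points <- transformPoints(t, points)
            points
          })

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "DisplacementFieldTransform",
          function(transform, points) {
            A <- transform@fieldDirection %*% diag(transform@fieldSpacing)
            idx0 <- sweep(points, 2L, transform@fieldOrigin, "-") %*%
              t(solve(A))
            d <- dim(transform@field)
            disp <- vapply(1:3, function(k)
              interpTrilinear(array(transform@field[, , , k], d[1:3]), idx0),
              numeric(nrow(points)))
            points + disp
          })

# Cubic B-spline basis weights for fractional offsets t in [0, 1):
# columns correspond to control points i-1, i, i+1, i+2.
cubicBsplineWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (4 - 6 * t2 + 3 * t3) / 6,
        (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
        t3 / 6)
}

# Per-axis support indices and weights for B-spline evaluation at points.
# Returns, for each axis, the 1-based index of the first of the four
# supporting control points (clamped into the grid) and the 4 weights.
bsplineSupport <- function(transform, points) {
  lapply(1:3, function(ax) {
    u <- (points[, ax] - transform@gridOrigin[ax]) /
      transform@gridSpacing[ax]
    i0 <- floor(u)
    t <- u - i0
    # control point (i0 - 1 .. i0 + 2) zero-based -> need i0 in [1, n-3]
    # for full support; clamp (points outside the padded grid are rare)
    n <- transform@gridDim[ax]
    i0c <- pmin(pmax(i0, 1), n - 3)
    t <- pmin(pmax(u - i0c, 0), 1)
    list(first = i0c, w = cubicBsplineWeights(t))
  })
}

# Displacement (n x 3, mm) of a B-spline FFD at physical points.
bsplineDisplacement <- function(transform, points) {
  sup <- bsplineSupport(transform, points)
  nd <- transform@gridDim
  disp <- matrix(0, nrow(points), 3)
  for (kz in 0:3) for (ky in 0:3) for (kx in 0:3) {
    w <- sup[[1]]$w[, kx + 1] * sup[[2]]$w[, ky + 1] * sup[[3]]$w[, kz + 1]
    lin <- (sup[[1]]$first + kx) +
      nd[1] * (sup[[2]]$first + ky - 1) +
      nd[1] * nd[2] * (sup[[3]]$first + kz - 1)
    disp <- disp + w * transform@coefficients[lin, , drop = FALSE]
  }
  disp
}

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "BSplineTransform",
          function(transform, points)
            points + bsplineDisplacement(transform, points))

#' @rdname SpatialTransform-class
#' @param object A transform.
#' @export
setMethod("show", "SpatialTransform", function(object) {
  cat(describeTransform(object), "\n")
})

describeTransform <- function(t) {
  if (is(t, "IdentityTransform")) return("identity")
  if (is(t, "TranslationTransform"))
    return(sprintf("translation (%.2f, %.2f, %.2f) mm",
                   t@offset[1], t@offset[2], t@offset[3]))
  if (is(t, "BSplineTransform"))
    return(sprintf("B-spline FFD %dx%dx%d control points, max |u| %.2f mm",
                   t@gridDim[1], t@gridDim[2], t@gridDim[3],
                   max(sqrt(rowSums(t@coefficients^2)))))
  if (is(t, "DisplacementFieldTransform")) {
    d <- dim(t@field)
    return(sprintf("displacement field %dx%dx%d, max |u| %.2f mm",
                   d[1], d[2], d[3],
                   max(sqrt(apply(t@field^2, c(1, 2, 3), sum)))))
  }
  if (is(t, "CompositeTransform"))
    return(paste("composite:",
                 paste(vapply(t@transforms, describeTransform,
                              character(1)), collapse = " then ")))
  class(t)[1]
}

#' Resample a label volume through a transform
#'
#' Warps \code{labels} (the moving image) onto the grid of
#' \code{reference} (the fixed image) with nearest-neighbour interpolation,
#' so no label values are invented; voxels mapping outside the input extent
#' become background (0).
#'
#' @param labels Moving \linkS4class{LabelVolume}.
#' @param transform A \linkS4class{SpatialTransform} mapping fixed-space
#'   points to moving-space sampling points.
#' @param reference A \linkS4class{LabelVolume} or
#'   \linkS4class{ImageVolume} whose grid defines the output.
#' @param chunk Number of voxels mapped per block (memory control).
#' @return A \linkS4class{LabelVolume} on the reference grid.
#' @export
applyTransformLabels <- function(labels, transform, reference,
                                 chunk = 400000L) {
  if (is(transform, "IdentityTransform") && sameGeometry(labels, reference))
    return(labelVolume(labels@voxels, reference@spacing, reference@origin,
                       reference@direction))
  dRef <- dim(reference@voxels)
  dMov <- dim(labels@voxels)
  nvox <- prod(dRef)
  out <- integer(nvox)
  mov <- labels@voxels
  for (start in seq(1L, nvox, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nvox)
    ijk <- arrayInd(idx, dRef) - 1L
    p <- voxelToPhys(reference, ijk)
    q <- transformPoints(transform, p)
    v <- physToVoxel(labels, q)
    iv <- round(v) + 1L
    ok <- iv[, 1] >= 1L & iv[, 1] <= dMov[1] &
          iv[, 2] >= 1L & iv[, 2] <= dMov[2] &
          iv[, 3] >= 1L & iv[, 3] <= dMov[3]
    lin <- iv[ok, 1] + dMov[1] * (iv[ok, 2] - 1L) +
      dMov[1] * dMov[2] * (iv[ok, 3] - 1L)
    out[idx[ok]] <- mov[lin]
  }
  labelVolume(array(out, dRef), reference@spacing, reference@origin,
              reference@direction)
}

#' Resample a scalar image through a transform
#'
#' Trilinear counterpart of \code{\link{applyTransformLabels}} for
#' anatomical images.
#'
#' @inheritParams applyTransformLabels
#' @param image Moving \linkS4class{ImageVolume}.
#' @return An \linkS4class{ImageVolume} on the reference grid.
#' @export
applyTransformImage <- function(image, transform, reference,
                                chunk = 400000L) {
  dRef <- dim(reference@voxels)
  nvox <- prod(dRef)
  out <- numeric(nvox)
  for (start in seq(1L, nvox, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nvox)
    ijk <- arrayInd(idx, dRef) - 1L
    p <- voxelToPhys(reference, ijk)
    q <- transformPoints(transform, p)
    v <- physToVoxel(image, q)
    out[idx] <- interpTrilinear(image@voxels, v, border = "zero")
  }
  imageVolume(array(out, dRef), reference@spacing, reference@origin,
              reference@direction)
}
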