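#' Translation-only alignment of two binary masks
#'
#' The rigid initialisation of the matching pipeline: a pure translation
#' taking the moving mask's physical centroid onto the fixed mask's
#' centroid. Deterministic and closed-form; organ/bone masks (user-supplied
#' or the CT surrogate from \code{\link{boneMaskFromCT}}) are the intended
#' inputs.
#'
#' @param fixedMask,movingMask Binary \linkS4class{LabelVolume}s (any
#'   positive voxel counts as foreground); both must be non-empty.
#' @return A \linkS4class{TranslationTransform} whose
#'   \code{\link{translation}} is the centroid difference (fixed minus
#'   moving), i.e. the shift applied to the moving image's content.
#' @examples
#' m <- array(0L, c(8, 8, 8)); m[3:4, 3:4, 3:4] <- 1L
#' translation(translationAlign(labelVolume(m), labelVolume(m)))
#' @export
translationAlign <- function(fixedMask, movingMask) {
  cf <- maskCentroid(fixedMask)
  cm <- maskCentroid(movingMask)
  translationTransform(cf - cm)
}

#' Surrogate bone mask from a CT image
#'
#' Thresholds the CT above a Hounsfield-unit cutoff and keeps connected
#' components at least \code{minVolumeCm3} large. A stand-in for dedicated
#' organ/bone contours when none are supplied to the pipeline.
#'
#' @param ct An \linkS4class{ImageVolume} in HU.
#' @param thresholdHU Intensity cutoff (default 200, cortical bone).
#' @param minVolumeCm3 Minimum component volume retained (default 10).
#' @param connectivity Component connectivity (default 26).
#' @return A binary \linkS4class{LabelVolume}.
#' @export
boneMaskFromCT <- function(ct, thresholdHU = 200, minVolumeCm3 = 10,
                           connectivity = 26L) {
  bin <- labelVolume(array(as.integer(ct@voxels > thresholdHU),
                           dim(ct@voxels)),
                     ct@spacing, ct@origin, ct@direction)
  lab <- labelComponents(bin, connectivity)
  vv <- voxelVolumeCm3(lab)
  counts <- tabulate(lab@voxels[lab@voxels > 0L])
  keep <- which(counts * vv >= minVolumeCm3)
  out <- array(as.integer(lab@voxels %in% keep & lab@voxels > 0L),
               dim(lab@voxels))
  labelVolume(out, ct@spacing, ct@origin, ct@direction)
}

# Physical-space intensity gradient arrays of a 3D image (central
# differences), returned as a list of three arrays.
imageGradientPhys <- function(arr, spacing, direction) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    gp <- array(0, d)
    n <- d[ax]
    idxHi <- c(2:n, n); idxLo <- c(1, 1:(n - 1))
    if (ax == 1) gp <- (arr[idxHi, , , drop = FALSE] -
                          arr[idxLo, , , drop = FALSE])
    if (ax == 2) gp <- (arr[, idxHi, , drop = FALSE] -
                          arr[, idxLo, , drop = FALSE])
    if (ax == 3) gp <- (arr[, , idxHi, drop = FALSE] -
                          arr[, , idxLo, drop = FALSE])
    step <- rep(2, n); step[c(1, n)] <- 1
    if (ax == 1) gp <- gp / (step * spacing[ax])
    if (ax == 2) gp <- sweep(gp, 2, step * spacing[ax], "/")
    if (ax == 3) gp <- sweep(gp, 3, step * spacing[ax], "/")
    dim(gp) <- d
    g[[ax]] <- gp
  }
  # voxel-axis gradients -> physical axes through the direction matrix
  if (max(abs(direction - diag(3))) > 1e-9) {
    gx <- g[[1]]; gy <- g[[2]]; gz <- g[[3]]
    for (k in 1:3)
      g[[k]] <- direction[k, 1] * gx + direction[k, 2] * gy +
        direction[k, 3] * gz
  }
  g
}

# Sparse cubic B-spline tensor weight matrix (n samples x n control points)
# for fixed sample positions; reused across optimiser iterations.
bsplineWeightMatrix <- function(transform, points) {
  sup <- bsplineSupport(transform, points)
  nd <- transform@gridDim
  n <- nrow(points)
  ii <- jj <- integer(64L * n)
  xx <- numeric(64L * n)
  pos <- 0L
  for (kz in 0:3) for (ky in 0:3) for (kx in 0:3) {
    w <- sup[[1]]$w[, kx + 1] * sup[[2]]$w[, ky + 1] * sup[[3]]$w[, kz + 1]
    lin <- (sup[[1]]$first + kx) +
      nd[1] * (sup[[2]]$first + ky - 1) +
      nd[1] * nd[2] * (sup[[3]]$first + kz - 1)
    ii[pos + seq_len(n)] <- seq_len(n)
    jj[pos + seq_len(n)] <- lin
    xx[pos + seq_len(n)] <- w
    pos <- pos + n
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n, prod(nd)))
}

#' Deformable B-spline registration
#'
#' Free-form deformation refinement after a rigid initialisation: cubic
#' B-spline control points on a regular physical grid are optimised (
#' L-BFGS-B, analytic gradient) to minimise the mean squared intensity
#' difference between the fixed image and the warped moving image, with a
#' light first-order smoothness penalty on the control-point displacements.
#' A multi-resolution pyramid (Gaussian smoothing plus sample striding)
#' provides robustness to moderate deformation. The procedure is fully
#' deterministic: samples are taken on a fixed stride, so repeated runs are
#' bit-identical.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s (same modality).
#' @param init A \linkS4class{SpatialTransform} applied before the FFD
#'   (typically from \code{\link{translationAlign}}).
#' @param gridSpacingMm Control-point spacing in mm (default 50).
#' @param iterations Optimiser iterations per level (default 40).
#' @param levels Resolution levels (default 3).
#' @param metric Similarity metric; \code{"msd"} (mean squared difference)
#'   is implemented.
#' @param sampleBudget Approximate number of fixed-image samples at the
#'   finest level.
#' @param smoothness Weight of the first-order control-point penalty.
#' @return A \linkS4class{CompositeTransform}: \code{init} followed by the
#'   fitted \linkS4class{BSplineTransform}.
#' @export
deformableRegister <- function(fixed, moving, init = identityTransform(),
                               gridSpacingMm = 50, iterations = 40L,
                               levels = 3L, metric = "msd",
                               sampleBudget = 60000L, smoothness = 1e-4) {
  if (!identical(metric, "msd"))
    capabilityError(paste0(
      "similarity metric '%s' is not available; use metric = \"msd\", or ",
      "supply a precomputed displacement field (registration mode ",
      "\"field\") or mode \"identity\""), metric)
  dFix <- dim(fixed@voxels)
  # FFD control grid: covers the init-mapped fixed extent, padded by one
  # spacing so every sample has full cubic support.
  corners0 <- as.matrix(expand.grid(c(0, dFix[1] - 1), c(0, dFix[2] - 1),
                                    c(0, dFix[3] - 1)))
  cornersP <- transformPoints(init, voxelToPhys(fixed, corners0))
  h <- rep(gridSpacingMm, 3)
  lo <- apply(cornersP, 2, min) - 2 * h
  hi <- apply(cornersP, 2, max) + 2 * h
  nd <- pmax(4L, as.integer(ceiling((hi - lo) / h)) + 1L)
  ffd <- new("BSplineTransform", gridOrigin = lo, gridSpacing = h,
             gridDim = nd, coefficients = matrix(0, prod(nd), 3))
  ncp <- prod(nd)
  # smoothness penalty: squared differences of neighbouring control points
  penaltyPairs <- local({
    idx <- array(seq_len(ncp), nd)
    p <- NULL
    p <- rbind(p, cbind(as.vector(idx[-nd[1], , ]), as.vector(idx[-1, , ])))
    p <- rbind(p, cbind(as.vector(idx[, -nd[2], ]), as.vector(idx[, -1, ])))
    p <- rbind(p, cbind(as.vector(idx[, , -nd[3]]), as.vector(idx[, , -1])))
    p
  })
  baseStride <- max(2L, ceiling((prod(dFix) / sampleBudget)^(1 / 3)))
  C <- ffd@coefficients
  for (lev in seq(levels, 1L)) {
    stride <- baseStride * 2L^(lev - 1L)
    sigmaVox <- rep(stride / 2, 3)
    fSm <- gaussianSmooth3(fixed@voxels, sigmaVox)
    mSm <- gaussianSmooth3(moving@voxels, sigmaVox)
    grad <- imageGradientPhys(mSm, moving@spacing, moving@direction)
    sIdx <- as.matrix(expand.grid(seq(1L, dFix[1], by = stride),
                                  seq(1L, dFix[2], by = stride),
                                  seq(1L, dFix[3], by = stride)))
    fVal <- fSm[sIdx]
    yPhys <- voxelToPhys(fixed, sIdx - 1L)
    z <- transformPoints(init, yPhys)
    # overlap check after initialisation
    vz <- physToVoxel(moving, z)
    inFrac <- mean(vz[, 1] > -1 & vz[, 1] < dim(moving@voxels)[1] &
                   vz[, 2] > -1 & vz[, 2] < dim(moving@voxels)[2] &
                   vz[, 3] > -1 & vz[, 3] < dim(moving@voxels)[3])
    if (inFrac < 0.05)
      registrationError(
        "images do not overlap after initialisation (%.1f%% inside)",
        100 * inFrac)
    W <- bsplineWeightMatrix(ffd, z)
    n <- nrow(z)
    scale2 <- stats::var(fVal) + 1e-12
    lam <- smoothness * scale2
    objective <- function(par) {
      Cm <- matrix(par, ncp, 3)
      q <- z + as.matrix(W %*% Cm)
      vq <- physToVoxel(moving, q)
      r <- interpTrilinear(mSm, vq) - fVal
      pen <- sum((Cm[penaltyPairs[, 1], ] - Cm[penaltyPairs[, 2], ])^2)
      mean(r^2) + lam * pen / ncp
    }
    gradient <- function(par) {
      Cm <- matrix(par, ncp, 3)
      q <- z + as.matrix(W %*% Cm)
      vq <- physToVoxel(moving, q)
      r <- interpTrilinear(mSm, vq) - fVal
      g <- vapply(1:3, function(k)
        as.numeric(Matrix::crossprod(
          W, r * interpTrilinear(grad[[k]], vq))) * 2 / n,
        numeric(ncp))
      dp <- Cm[penaltyPairs[, 1], , drop = FALSE] -
        Cm[penaltyPairs[, 2], , drop = FALSE]
      acc <- rowsum(rbind(dp, -dp),
                    group = c(penaltyPairs[, 1], penaltyPairs[, 2]))
      gp <- matrix(0, ncp, 3)
      gp[as.integer(rownames(acc)), ] <- acc
      as.numeric(g + lam * 2 * gp / ncp)
    }
    fit <- stats::optim(as.numeric(C), objective, gradient,
                        method = "L-BFGS-B",
                        control = list(maxit = iterations))
    C <- matrix(fit$par, ncp, 3)
  }
  ffd@coefficients <- C
  compositeTransform(init, ffd)
}
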