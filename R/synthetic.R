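generationError <- function(fmt, ...) lgStop("lesiongraph_generation_error",
                                             fmt, ...)

#' Specify a synthetic longitudinal phantom
#'
#' Defaults describe a desk-scale but realistic scan pair: a
#' 256x256x160 mm field of view at 2 mm isotropic spacing, ten ellipsoidal
#' lesions with volumes drawn log-uniformly from 0.05-2 cm^3 (straddling
#' the 0.1 cm^3 analysis threshold so volume filtering is exercised), a
#' smooth sinusoidal inter-scan deformation of 8 mm amplitude and 150 mm
#' wavelength, and modest lesion appearance/disappearance/split/merge
#' rates.
#'
#' @param gridShape,spacingMm Voxel grid and spacing.
#' @param nLesions Number of scan-1 lesions.
#' @param volumeRangeCm3 Lesion volume range (cm^3), log-uniform draw.
#' @param pDisappear,pNew,pSplit,pMerge Per-lesion event probabilities.
#' @param deformationAmplitudeMm,deformationWavelengthMm Deformation
#'   parameters (mm).
#' @param minSeparationMm Minimum centre separation of independently
#'   placed lesions; the default keeps dilated lesions (25 mm) of distinct
#'   truth pairs from clustering, so recovery errors reflect the matcher,
#'   not packing.
#' @param seed Integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(128L, 128L, 80L),
                        spacingMm = c(2, 2, 2), nLesions = 10L,
                        volumeRangeCm3 = c(0.05, 2), pDisappear = 0.15,
                        pNew = 0.15, pSplit = 0.05, pMerge = 0.05,
                        deformationAmplitudeMm = 8,
                        deformationWavelengthMm = 150,
                        minSeparationMm = 66, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), nLesions = as.integer(nLesions),
      volumeRangeCm3 = as.numeric(volumeRangeCm3),
      pDisappear = pDisappear, pNew = pNew, pSplit = pSplit,
      pMerge = pMerge,
      deformationAmplitudeMm = deformationAmplitudeMm,
      deformationWavelengthMm = deformationWavelengthMm,
      minSeparationMm = minSeparationMm, seed = as.integer(seed))
}

# Voxels (1-based ijk matrix) whose centres fall inside an axis-aligned
# ellipsoid; origin 0 / identity orientation grid.
ellipsoidVoxels <- function(center, axes, spacing, gridDim) {
  lo <- pmax(1L, floor((center - axes) / spacing) + 1L)
  hi <- pmin(gridDim, ceiling((center + axes) / spacing) + 1L)
  if (any(hi < lo)) return(matrix(integer(0), ncol = 3))
  g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  p <- sweep(g - 1L, 2L, spacing, "*")
  d <- sweep(p, 2L, center, "-")
  r2 <- (d[, 1] / axes[1])^2 + (d[, 2] / axes[2])^2 + (d[, 3] / axes[3])^2
  g[r2 <= 1, , drop = FALSE]
}

# Rasterise an ellipsoid of target volume, rescaling so the voxelised
# volume lands within the requested band (discretisation can otherwise
# overshoot for few-voxel lesions).
rasterizeLesion <- function(center, axes, targetCm3, bandCm3, spacing,
                            gridDim) {
  vv <- prod(spacing) / 1000
  ax <- axes
  for (it in 1:12) {
    vox <- ellipsoidVoxels(center, ax, spacing, gridDim)
    got <- nrow(vox) * vv
    if (nrow(vox) >= 1L && got >= bandCm3[1] && got <= bandCm3[2])
      return(vox)
    scale <- (targetCm3 / max(got, vv / 2))^(1 / 3)
    scale <- min(max(scale, 0.7), 1.4)
    ax <- ax * scale
  }
  vox
}

# Smooth band-limited deformation: per-component single-frequency sinusoid
# of a transverse coordinate, maximum magnitude <= amplitude.
makeDeformation <- function(amplitude, wavelength, phases) {
  a <- amplitude / sqrt(3)
  force(wavelength)
  function(p) {
    if (amplitude == 0) return(p)
    p + cbind(a * sin(2 * pi * p[, 2] / wavelength + phases[1]),
              a * sin(2 * pi * p[, 3] / wavelength + phases[2]),
              a * sin(2 * pi * p[, 1] / wavelength + phases[3]))
  }
}

randomUnit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Background texture: random low-frequency cosine field defined in scan-2
# space, evaluated analytically wherever needed (no inversion of the
# deformation required).
makeBackground <- function(nComp = 24L) {
  dirs <- t(vapply(seq_len(nComp), function(i) randomUnit(), numeric(3)))
  lam <- stats::runif(nComp, 40, 160)
  phi <- stats::runif(nComp, 0, 2 * pi)
  w <- stats::rnorm(nComp, 0, 12)
  function(p) {
    out <- numeric(nrow(p))
    for (m in seq_len(nComp))
      out <- out + w[m] * cos(2 * pi * (p %*% dirs[m, ]) / lam[m] + phi[m])
    as.numeric(out) - 30
  }
}

placePoint <- function(bounds, existing, minDist, maxTries = 4000L) {
  for (t in seq_len(maxTries)) {
    p <- c(stats::runif(1, bounds[1, 1], bounds[2, 1]),
           stats::runif(1, bounds[1, 2], bounds[2, 2]),
           stats::runif(1, bounds[1, 3], bounds[2, 3]))
    if (!nrow(existing) ||
        min(sqrt(rowSums(sweep(existing, 2L, p, "-")^2))) >= minDist)
      return(p)
  }
  generationError(paste0("could not place a lesion with %.0f mm ",
                         "separation after %d attempts: grid too small ",
                         "for the requested lesion count"),
                  minDist, maxTries)
}

#' Generate a synthetic longitudinal scan pair with ground truth
#'
#' Builds scan 1 (CT + lesion label map), a smoothly deformed scan 2 with
#' per-lesion events applied (disappearance, appearance, splits into
#' fragments inside the parent's footprint, merges bridged into one
#' lesion), the exact ground-truth match graph including sentinel edges,
#' and the true displacement field on the scan-1 grid (adding the field to
#' a scan-1 point gives the corresponding scan-2 point, ready for
#' \code{\link{matchPipeline}}'s \code{field} argument).
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param images Synthesise the CT images (set \code{FALSE} to skip them
#'   when only label maps, truth and field are needed; the label maps,
#'   truth graph and field are unaffected).
#' @return List with \code{ct1}, \code{labels1}, \code{ct2},
#'   \code{labels2}, \code{truth} (a \linkS4class{MatchGraph}),
#'   \code{field} (a \linkS4class{DisplacementFieldTransform}), and
#'   \code{info} (events, lesion centres in both scans, volumes).
#' @export
generatePhantomPair <- function(spec, images = TRUE) {
  withSeed(spec@seed, generatePhantomPairImpl(spec, images))
}

generatePhantomPairImpl <- function(spec, images = TRUE) {
  gd <- spec@gridShape
  sp <- spec@spacingMm
  fov <- (gd - 1L) * sp
  n <- spec@nLesions
  vv <- prod(sp) / 1000
  band <- c(spec@volumeRangeCm3[1] - vv, spec@volumeRangeCm3[2] + vv)

  # --- events -------------------------------------------------------------
  u <- stats::runif(max(n, 1))
  roles <- rep("carry", n)
  if (n) {
    roles[u[seq_len(n)] < spec@pDisappear + spec@pSplit] <- "split"
    roles[u[seq_len(n)] < spec@pDisappear] <- "disappear"
  }
  carry <- which(roles == "carry")
  mergeCand <- carry[stats::runif(length(carry)) < spec@pMerge]
  mergePairs <- NULL
  while (length(mergeCand) >= 2) {
    mergePairs <- rbind(mergePairs, mergeCand[1:2])
    mergeCand <- mergeCand[-(1:2)]
  }
  isMergeSecondary <- logical(n)
  if (!is.null(mergePairs)) isMergeSecondary[mergePairs[, 2]] <- TRUE
  nNew <- stats::rbinom(1, max(n, 1L), spec@pNew)

  # --- scan-1 lesion geometry ---------------------------------------------
  vols <- exp(stats::runif(n + nNew, log(spec@volumeRangeCm3[1]),
                           log(spec@volumeRangeCm3[2])))
  radii <- (3 * vols * 1000 / (4 * pi))^(1 / 3)
  axesList <- lapply(seq_len(n + nNew), function(i) {
    f <- exp(stats::runif(3, -0.2, 0.2))
    radii[i] * f / prod(f)^(1 / 3)
  })
  margin <- max(radii) + spec@deformationAmplitudeMm + 2 * max(sp)
  if (any(fov <= 2 * margin))
    generationError("grid too small for the requested lesion sizes")
  bounds <- rbind(margin, fov - margin)
  centers <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    if (isMergeSecondary[i]) {
      prim <- mergePairs[mergePairs[, 2] == i, 1]
      gap <- max(radii[prim] + radii[i] + 10, 1.2 * (radii[prim] + radii[i]))
      for (t in 1:200) {
        p <- centers[prim, ] + randomUnit() * gap
        ok <- all(p > bounds[1, ]) && all(p < bounds[2, ])
        others <- centers[-prim, , drop = FALSE]
        if (ok && (!nrow(others) ||
                   min(sqrt(rowSums(sweep(others, 2L, p, "-")^2))) >=
                     spec@minSeparationMm)) break
        p <- NULL
      }
      if (is.null(p))
        generationError("could not place merge partner for lesion %d", prim)
    } else {
      p <- placePoint(bounds, centers, spec@minSeparationMm)
    }
    centers <- rbind(centers, p)
  }
  newCenters <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nNew)) {
    p <- placePoint(bounds, rbind(centers, newCenters),
                    spec@minSeparationMm)
    newCenters <- rbind(newCenters, p)
  }

  # --- deformation ---------------------------------------------------------
  phases <- stats::runif(3, 0, 2 * pi)
  g <- makeDeformation(spec@deformationAmplitudeMm,
                       spec@deformationWavelengthMm, phases)

  # --- rasterise scan 1 ----------------------------------------------------
  lab1 <- array(0L, gd)
  vox1 <- vector("list", n)
  for (i in seq_len(n)) {
    vox <- rasterizeLesion(centers[i, ], axesList[[i]], vols[i], band, sp,
                           gd)
    if (!nrow(vox))
      generationError("lesion %d rasterised to zero voxels", i)
    lab1[vox] <- i
    vox1[[i]] <- vox
  }

  # --- compose scan 2 ------------------------------------------------------
  lab2 <- array(0L, gd)
  matches <- matrix(integer(0), ncol = 2)
  k <- 0L
  centers2 <- matrix(numeric(0), ncol = 3)
  mapped <- if (n) g(centers) else centers
  addLesion <- function(vox) {
    k <<- k + 1L
    lab2[vox] <<- k
    k
  }
  splitFragments <- function(i) {
    cP <- mapped[i, ]
    vF <- vols[i] * c(0.38, 0.3)
    rF <- (3 * vF * 1000 / (4 * pi))^(1 / 3)
    e <- randomUnit()
    off <- (rF[1] + rF[2] + 2.5 * max(sp)) / 2
    for (f in 1:2) {
      cF <- cP + (if (f == 1) off else -off) * e
      vox <- rasterizeLesion(cF, rep(rF[f], 3), vF[f],
                             c(vv / 2, band[2]), sp, gd)
      id <- addLesion(vox)
      matches <<- rbind(matches, c(i, id))
      centers2 <<- rbind(centers2, cF)
    }
  }
  for (i in seq_len(n)) {
    if (roles[i] == "disappear" || isMergeSecondary[i]) next
    if (roles[i] == "split") {
      splitFragments(i)
      next
    }
    if (!is.null(mergePairs) && i %in% mergePairs[, 1]) {
      j <- mergePairs[mergePairs[, 1] == i, 2]
      va <- ellipsoidVoxels(mapped[i, ], axesList[[i]], sp, gd)
      vb <- ellipsoidVoxels(mapped[j, ], axesList[[j]], sp, gd)
      vbr <- bridgeVoxels(mapped[i, ], mapped[j, ],
                          max(1.2 * max(sp),
                              0.4 * min(axesList[[i]], axesList[[j]])),
                          sp, gd)
      vox <- unique(rbind(va, vb, vbr))
      id <- addLesion(vox)
      matches <- rbind(matches, c(i, id), c(j, id))
      centers2 <- rbind(centers2, (mapped[i, ] + mapped[j, ]) / 2)
      next
    }
    vox <- rasterizeLesion(mapped[i, ], axesList[[i]], vols[i], band, sp,
                           gd)
    id <- addLesion(vox)
    matches <- rbind(matches, c(i, id))
    centers2 <- rbind(centers2, mapped[i, ])
  }
  if (nNew > 0) for (i in seq_len(nNew)) {
    cN <- g(newCenters)[i, ]
    vox <- rasterizeLesion(cN, axesList[[n + i]], vols[n + i], band, sp, gd)
    addLesion(vox)
    centers2 <- rbind(centers2, cN)
  }
  truth <- buildGraph(seq_len(n), seq_len(k), matches)

  # --- displacement field on the scan-1 grid -------------------------------
  fieldArr <- array(0, c(gd, 3L))
  for (zz in seq_len(gd[3])) {
    sl <- as.matrix(expand.grid(seq_len(gd[1]), seq_len(gd[2]), zz))
    p <- sweep(sl - 1L, 2L, sp, "*")
    d <- g(p) - p
    for (cmp in 1:3)
      fieldArr[, , zz, cmp] <- d[, cmp]
  }
  field <- displacementFieldTransform(fieldArr, sp, c(0, 0, 0), diag(3))

  # --- CT images -----------------------------------------------------------
  ct1 <- ct2 <- NULL
  if (images) {
  B <- makeBackground()
  # spine-like bone rod (defined in scan-2 space, like the background, so
  # both images are consistent under the deformation): gives the >200 HU
  # structure the surrogate bone mask and the registration rely on
  rodXY <- c(0.5, 0.35) * fov[1:2]
  boneHU <- function(p) {
    d <- sqrt((p[, 1] - rodXY[1])^2 + (p[, 2] - rodXY[2])^2)
    1100 * (d <= 12)
  }
  nvox <- prod(gd)
  ctOf <- function(labels, warpToScan2) {
    out <- numeric(nvox)
    chunk <- 300000L
    for (s in seq(1L, nvox, by = chunk)) {
      idx <- s:min(s + chunk - 1L, nvox)
      p <- sweep(arrayInd(idx, gd) - 1L, 2L, sp, "*")
      if (warpToScan2) p <- g(p)
      out[idx] <- B(p) + boneHU(p)
    }
    arr <- array(out, gd) + 90 * (labels > 0L)
    arr <- gaussianSmooth3(arr, rep(0.8, 3))
    arr + array(stats::rnorm(nvox, 0, 3), gd)
  }
  ct1 <- imageVolume(ctOf(lab1, TRUE), sp)
  ct2 <- imageVolume(ctOf(lab2, FALSE), sp)
  }

  list(ct1 = ct1,
       labels1 = labelVolume(lab1, sp),
       ct2 = ct2,
       labels2 = labelVolume(lab2, sp),
       truth = truth,
       field = field,
       info = list(roles = roles, mergePairs = mergePairs, nNew = nNew,
                   centers1 = centers, centers1Mapped = mapped,
                   centers2 = centers2, volumesCm3 = vols,
                   deform = g))
}

# Voxels within radius of the segment p1-p2 (the merge bridge).
bridgeVoxels <- function(p1, p2, radius, spacing, gridDim) {
  lo <- pmax(1L, floor((pmin(p1, p2) - radius) / spacing) + 1L)
  hi <- pmin(gridDim, ceiling((pmax(p1, p2) + radius) / spacing) + 1L)
  if (any(hi < lo)) return(matrix(integer(0), ncol = 3))
  gr <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  p <- sweep(gr - 1L, 2L, spacing, "*")
  v <- p2 - p1
  len2 <- sum(v^2)
  t <- pmin(pmax(as.numeric(sweep(p, 2L, p1, "-") %*% v) / len2, 0), 1)
  nearest <- outer(t, v) + matrix(p1, nrow(p), 3, byrow = TRUE)
  d2 <- rowSums((p - nearest)^2)
  gr[d2 <= radius^2, , drop = FALSE]
}

#' Score how well the matcher recovers a phantom's ground truth
#'
#' Generates a phantom pair, runs \code{\link{matchPipeline}} (with the
#' phantom's true displacement field when the configuration's registration
#' mode is \code{"field"}; otherwise registration runs as configured), and
#' compares the automated graph against the ground truth restricted to the
#' lesions the pipeline retained after volume filtering (the analysis
#' threshold applies to the evaluation as well as the method).
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param config A \linkS4class{MatchConfig}.
#' @return A \linkS4class{MetricsReport} (automated vs truth).
#' @export
truthRecoveryScore <- function(spec, config = matchConfig(regMode = "field")) {
  pair <- generatePhantomPair(spec, images = config@regMode == "auto")
  res <- matchPipeline(pair$labels1, pair$labels2,
                       ct1 = if (config@regMode == "auto") pair$ct1,
                       ct2 = if (config@regMode == "auto") pair$ct2,
                       field = if (config@regMode == "field") pair$field,
                       config = config)
  truthR <- restrictGraph(pair$truth, res$provenance$kept1,
                          res$provenance$kept2)
  compareGraphs(res$graph, truthR)
}
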