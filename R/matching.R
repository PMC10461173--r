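#' Construct a matcher configuration
#'
#' Defaults follow the published operating point of the matcher: 25 mm
#' dilation (optimal for absorbing registration uncertainty), a strict
#' 0.1 cm^3 volume threshold, 26-connectivity component labelling, and a
#' 50 mm B-spline control-point spacing.
#'
#' @param dilationMm Lesion dilation radius (mm).
#' @param minVolumeCm3 Strict lower volume threshold (cm^3).
#' @param connectivity 6, 18 or 26.
#' @param regMode Registration mode: \code{"auto"} (translation + B-spline
#'   when CT images are available, translation when only masks are,
#'   identity otherwise; a supplied displacement field always wins),
#'   \code{"field"} (require a precomputed displacement field),
#'   \code{"translation"}, or \code{"identity"}.
#' @param regGridSpacingMm,regMetric,regIterations,regLevels,regSeed
#'   Deformable-stage settings (see \code{\link{deformableRegister}}).
#' @return A \linkS4class{MatchConfig}.
#' @export
matchConfig <- function(dilationMm = 25, minVolumeCm3 = 0.1,
                        connectivity = 26L, regMode = "auto",
                        regGridSpacingMm = 50, regMetric = "msd",
                        regIterations = 40L, regLevels = 3L,
                        regSeed = 0L) {
  new("MatchConfig", dilationMm = dilationMm, minVolumeCm3 = minVolumeCm3,
      connectivity = as.integer(connectivity), regMode = regMode,
      regGridSpacingMm = regGridSpacingMm, regMetric = regMetric,
      regIterations = as.integer(regIterations),
      regLevels = as.integer(regLevels), regSeed = as.integer(regSeed))
}

#' @rdname matchConfig
#' @param path YAML configuration file with keys \code{dilation_mm},
#'   \code{min_volume_cm3}, \code{connectivity} and a \code{registration}
#'   block (\code{mode}, \code{grid_spacing_mm}, \code{metric},
#'   \code{seed}).
#' @export
readMatchConfig <- function(path) {
  y <- yaml::read_yaml(path)
  reg <- y$registration
  args <- list()
  if (!is.null(y$dilation_mm)) args$dilationMm <- y$dilation_mm
  if (!is.null(y$min_volume_cm3)) args$minVolumeCm3 <- y$min_volume_cm3
  if (!is.null(y$connectivity)) args$connectivity <- y$connectivity
  if (!is.null(reg$mode)) args$regMode <- reg$mode
  if (!is.null(reg$grid_spacing_mm)) args$regGridSpacingMm <- reg$grid_spacing_mm
  if (!is.null(reg$metric)) args$regMetric <- reg$metric
  if (!is.null(reg$seed)) args$regSeed <- reg$seed
  do.call(matchConfig, args)
}

configAsList <- function(config) {
  list(dilation_mm = config@dilationMm,
       min_volume_cm3 = config@minVolumeCm3,
       connectivity = config@connectivity,
       registration = list(mode = config@regMode,
                           grid_spacing_mm = config@regGridSpacingMm,
                           metric = config@regMetric,
                           iterations = config@regIterations,
                           levels = config@regLevels,
                           seed = config@regSeed))
}

#' Cluster lesions within one scan
#'
#' Clusters are the connected components of the within-scan graph linking
#' lesions whose dilated masks share at least one voxel; they let the
#' matcher treat lesions that merge or split between scans as a unit.
#' Clusters are ordered by their smallest member index (deterministic).
#'
#' @param lesions A \linkS4class{LesionSet} with dilated masks populated.
#' @return A ClusterSet: list with \code{clusters} (list of integer lesion
#'   index vectors), \code{masks} (cropped union-of-dilated-masks per
#'   cluster) and the grid geometry (\code{dim}, \code{spacing},
#'   \code{origin}, \code{direction}).
#' @export
clusterWithinScan <- function(lesions) {
  n <- length(lesions@indices)
  if (n && any(vapply(lesions@dilated, is.null, logical(1))))
    validationError("dilated masks missing: call dilateLesions() first")
  adj <- NULL
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      if (croppedOverlapCount(lesions@dilated[[a]],
                              lesions@dilated[[b]]) > 0L)
        adj <- rbind(adj, c(a, b))
  }
  memb <- if (n) {
    gr <- igraph::graph_from_edgelist(
      rbind(cbind(seq_len(n), seq_len(n)), adj), directed = FALSE)
    igraph::components(gr)$membership[seq_len(n)]
  } else integer(0)
  groups <- split(seq_len(n), memb)
  ord <- order(vapply(groups, function(g) min(lesions@indices[g]),
                      numeric(1)))
  groups <- groups[ord]
  list(clusters = lapply(groups, function(g) lesions@indices[g]),
       masks = lapply(groups, function(g) unionCropped(lesions@dilated[g])),
       dim = lesions@dim, spacing = lesions@spacing,
       origin = lesions@origin, direction = lesions@direction)
}

#' Cluster-pair intersection volumes
#'
#' Entry (i, j) is the physical volume (cm^3) of the voxel-wise
#' intersection of cluster i's mask on scan 1 with cluster j's mask on the
#' warped scan 2; both cluster sets must live on the same (scan-1) grid.
#'
#' @param c1,c2 ClusterSets from \code{\link{clusterWithinScan}}, on a
#'   common grid.
#' @return Non-negative numeric matrix, rows = scan-1 clusters.
#' @export
intersectionMatrix <- function(c1, c2) {
  if (!all(c1$dim == c2$dim) ||
      max(abs(c1$spacing - c2$spacing)) > 1e-6 ||
      max(abs(c1$origin - c2$origin)) > 1e-6 ||
      max(abs(c1$direction - c2$direction)) > 1e-6)
    validationError("cluster sets are not on the same grid")
  vv <- prod(c1$spacing) / 1000
  m <- matrix(0, length(c1$clusters), length(c2$clusters))
  for (i in seq_along(c1$clusters)) for (j in seq_along(c2$clusters))
    m[i, j] <- croppedOverlapCount(c1$masks[[i]], c2$masks[[j]]) * vv
  m
}

#' Expand a cluster assignment to lesion-level edges
#'
#' For each matched cluster pair, an edge is added for every member lesion
#' pair whose dilated masks intersect. A member lesion left without any
#' edge attaches to the counterpart-cluster lesion with maximal dilated
#' overlap, or becomes new/disappeared if all overlaps are zero. Lesions in
#' unmatched clusters become new/disappeared.
#'
#' @param pairs Two-column matrix of assigned (scan-1 cluster, scan-2
#'   cluster) positions, as from \code{\link{solveAssignment}}.
#' @param lesions1,lesions2 Dilated \linkS4class{LesionSet}s (scan 2
#'   warped onto the scan-1 grid).
#' @param c1,c2 The corresponding ClusterSets.
#' @return A valid \linkS4class{MatchGraph}.
#' @export
expandToLesionEdges <- function(pairs, lesions1, lesions2, c1, c2) {
  matches <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(pairs))) {
    mem1 <- c1$clusters[[pairs[r, 1]]]
    mem2 <- c2$clusters[[pairs[r, 2]]]
    ov <- matrix(0L, length(mem1), length(mem2))
    for (a in seq_along(mem1)) {
      da <- lesions1@dilated[[match(mem1[a], lesions1@indices)]]
      for (b in seq_along(mem2)) {
        db <- lesions2@dilated[[match(mem2[b], lesions2@indices)]]
        ov[a, b] <- croppedOverlapCount(da, db)
      }
    }
    for (a in seq_along(mem1)) for (b in seq_along(mem2))
      if (ov[a, b] > 0L)
        matches <- rbind(matches, c(mem1[a], mem2[b]))
    # leftover members: best counterpart by dilated overlap (sentinel if 0)
    for (a in which(rowSums(ov > 0L) == 0L))
      if (any(ov[a, ] > 0L))
        matches <- rbind(matches, c(mem1[a], mem2[which.max(ov[a, ])]))
    for (b in which(colSums(ov > 0L) == 0L))
      if (any(ov[, b] > 0L))
        matches <- rbind(matches, c(mem1[which.max(ov[, b])], mem2[b]))
  }
  buildGraph(lesions1@indices, lesions2@indices, matches)
}

resolveTransform <- function(config, ct1, ct2, mask1, mask2, field) {
  mode <- config@regMode
  if (mode == "identity") return(identityTransform())
  if (mode == "field") {
    if (is.null(field))
      capabilityError(paste0("registration mode 'field' requires a ",
                             "displacement field"))
    return(field)
  }
  if (mode == "auto" && !is.null(field)) return(field)
  haveMasks <- !is.null(mask1) && !is.null(mask2)
  haveCT <- !is.null(ct1) && !is.null(ct2)
  if (!haveMasks && haveCT) {
    mask1 <- boneMaskFromCT(ct1)
    mask2 <- boneMaskFromCT(ct2)
    haveMasks <- TRUE
  }
  if (!haveMasks) {
    if (mode == "translation")
      capabilityError(paste0("registration mode 'translation' requires ",
                             "organ/bone masks or CT images"))
    return(identityTransform())
  }
  init <- translationAlign(mask1, mask2)
  if (mode == "translation" || !haveCT) return(init)
  deformableRegister(ct1, ct2, init,
                     gridSpacingMm = config@regGridSpacingMm,
                     iterations = config@regIterations,
                     levels = config@regLevels,
                     metric = config@regMetric)
}

#' Run the full automated lesion-matching pipeline
#'
#' The four-step matcher: (1) register scan 2 (moving) to scan 1 (fixed)
#' and resample its label map onto the scan-1 grid with nearest-neighbour
#' interpolation; (2) index lesions by connected components (when the
#' inputs are binary), drop lesions at or below the volume threshold, and
#' dilate the survivors; (3) cluster lesions within each scan by dilated
#' overlap; (4) assign clusters one-to-one by Munkres maximising
#' intersection volume and expand the assignment to lesion-level edges.
#' Repeated runs on identical inputs and configuration produce identical
#' graphs.
#'
#' @param scan1Labels,scan2Labels \linkS4class{LabelVolume}s: lesion label
#'   maps (or binary masks) of the two scans.
#' @param ct1,ct2 Optional \linkS4class{ImageVolume}s driving the
#'   deformable registration.
#' @param mask1,mask2 Optional organ/bone masks for the translation
#'   initialisation (a >200 HU surrogate is derived from CT when absent).
#' @param field Optional \linkS4class{DisplacementFieldTransform} (or any
#'   \linkS4class{SpatialTransform}) used instead of running registration.
#' @param config A \linkS4class{MatchConfig}.
#' @return List with \code{graph} (a \linkS4class{MatchGraph}) and
#'   \code{provenance} (configuration echo, transform summary, per-stage
#'   lesion/cluster counts, kept lesion indices, and wall-clock duration).
#' @export
matchPipeline <- function(scan1Labels, scan2Labels, ct1 = NULL, ct2 = NULL,
                          mask1 = NULL, mask2 = NULL, field = NULL,
                          config = matchConfig()) {
  t0 <- proc.time()[["elapsed"]]
  transform <- resolveTransform(config, ct1, ct2, mask1, mask2, field)
  warped2 <- applyTransformLabels(scan2Labels, transform, scan1Labels)
  lab1 <- scan1Labels
  if (length(labelValues(lab1)) <= 1L && any(lab1@voxels > 0L))
    lab1 <- labelComponents(lab1, config@connectivity)
  lab2 <- warped2
  if (length(labelValues(lab2)) <= 1L && any(lab2@voxels > 0L))
    lab2 <- labelComponents(lab2, config@connectivity)
  ls1 <- lesionSet(lab1)
  ls2 <- lesionSet(lab2)
  n1All <- ls1@indices; n2All <- ls2@indices
  ls1 <- filterByVolume(ls1, config@minVolumeCm3)
  ls2 <- filterByVolume(ls2, config@minVolumeCm3)
  ls1 <- dilateLesions(ls1, config@dilationMm)
  ls2 <- dilateLesions(ls2, config@dilationMm)
  c1 <- clusterWithinScan(ls1)
  c2 <- clusterWithinScan(ls2)
  ov <- intersectionMatrix(c1, c2)
  asg <- solveAssignment(ov)
  graph <- expandToLesionEdges(asg$pairs, ls1, ls2, c1, c2)
  prov <- list(
    config = configAsList(config),
    transform = describeTransform(transform),
    counts = list(scan1_lesions = length(n1All),
                  scan2_lesions = length(n2All),
                  scan1_kept = length(ls1@indices),
                  scan2_kept = length(ls2@indices),
                  scan1_clusters = length(c1$clusters),
                  scan2_clusters = length(c2$clusters),
                  assigned_cluster_pairs = nrow(asg$pairs)),
    kept1 = ls1@indices, kept2 = ls2@indices,
    assigned_overlap_cm3 = asg$total,
    duration_sec = proc.time()[["elapsed"]] - t0)
  list(graph = graph, provenance = prov)
}
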