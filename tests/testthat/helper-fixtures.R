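# Shared fixtures and independent oracles. Phantoms are cached per session
# so expensive generations run once.

.fixtures <- new.env(parent = emptyenv())

cachedPhantom <- function(key, spec, images = FALSE) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantomPair(spec, images = images)
  .fixtures[[key]]
}

# Small, well-separated phantom: identity deformation, no events, so the
# truth is the identity one-to-one graph and singleton clusters.
calmSpec <- function(seed = 5L, n = 4L, amplitude = 0)
  phantomSpec(gridShape = c(64L, 64L, 48L), spacingMm = c(3, 3, 3),
              nLesions = n, volumeRangeCm3 = c(0.3, 1.5),
              pDisappear = 0, pNew = 0, pSplit = 0, pMerge = 0,
              deformationAmplitudeMm = amplitude, seed = seed)

# Registration-scale phantom with CT images (cached with images).
regSpec <- function(seed = 11L, amplitude = 8)
  phantomSpec(gridShape = c(96L, 96L, 48L), spacingMm = c(2.5, 2.5, 2.5),
              nLesions = 6L, volumeRangeCm3 = c(0.3, 3),
              pDisappear = 0, pNew = 0, pSplit = 0, pMerge = 0,
              deformationAmplitudeMm = amplitude, seed = seed)

# The standard recovery conditions: 20 lesions, 12 mm deformation.
recoverySpec <- function(seed)
  phantomSpec(gridShape = c(160L, 160L, 112L),
              spacingMm = c(2.5, 2.5, 2.5), nLesions = 20L,
              deformationAmplitudeMm = 12, seed = as.integer(seed))

# Uniform draw of one element from a vector (safe for length-1 vectors,
# where sample() would draw from 1:x).
pickOne <- function(x) x[sample.int(length(x), 1)]

# Random valid match graph over random index sets (splits/merges allowed).
randomGraph <- function(maxN = 8L) {
  n1 <- sort(sample.int(3L * maxN, sample.int(maxN, 1)))
  n2 <- sort(sample.int(3L * maxN, sample.int(maxN, 1)))
  m <- NULL
  for (i in n1)
    if (stats::runif(1) < 0.7 && length(n2))
      m <- rbind(m, c(i, pickOne(n2)))
  # occasional extra edge to exercise one-to-many
  if (!is.null(m) && stats::runif(1) < 0.3 && length(n2))
    m <- rbind(m, c(m[1, 1], pickOne(n2)))
  buildGraph(n1, n2, unique(m))
}

# Exhaustive assignment oracle: enumerates every partial one-to-one
# assignment with positive-overlap cells, maximising total overlap and
# breaking ties lexicographically (rows in order; a matched row precedes an
# unmatched one at the first difference).
exhaustiveAssignment <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- list(total = -Inf, pairs = NULL)
  better <- function(tot, pairs) {
    if (tot > best$total + 1e-9) return(TRUE)
    if (tot < best$total - 1e-9) return(FALSE)
    a <- pairs; b <- best$pairs
    la <- if (is.null(a)) 0L else nrow(a)
    lb <- if (is.null(b)) 0L else nrow(b)
    for (k in seq_len(max(la, lb))) {
      if (k > la) return(FALSE)  # a ended first: a is larger
      if (k > lb) return(TRUE)   # b ended first: a is smaller
      if (a[k, 1] != b[k, 1]) return(a[k, 1] < b[k, 1])
      if (a[k, 2] != b[k, 2]) return(a[k, 2] < b[k, 2])
    }
    FALSE
  }
  recurse <- function(row, usedCols, pairs, tot) {
    if (row > nr) {
      if (better(tot, pairs)) best <<- list(total = tot, pairs = pairs)
      return(invisible())
    }
    recurse(row + 1L, usedCols, pairs, tot)
    for (j in seq_len(nc))
      if (!usedCols[j] && w[row, j] > 0)
        recurse(row + 1L, replace(usedCols, j, TRUE),
                rbind(pairs, c(row, j)), tot + w[row, j])
    invisible()
  }
  recurse(1L, logical(nc), NULL, 0)
  if (is.null(best$pairs)) best$pairs <- matrix(integer(0), ncol = 2)
  best$total <- max(best$total, 0)
  best
}

# Brute-force dilation oracle: every voxel within radiusMm (physical,
# centre-to-centre) of some lesion voxel.
bruteDilate <- function(maskArr, spacing, radiusMm) {
  d <- dim(maskArr)
  fg <- which(maskArr > 0)
  fp <- sweep(arrayInd(fg, d) - 1L, 2L, spacing, "*")
  out <- array(FALSE, d)
  all3 <- arrayInd(seq_len(prod(d)), d)
  ap <- sweep(all3 - 1L, 2L, spacing, "*")
  for (v in seq_len(prod(d))) {
    dd <- sweep(fp, 2L, ap[v, ], "-")
    if (min(rowSums(dd^2)) <= radiusMm^2 + 1e-9) out[v] <- TRUE
  }
  out
}

# Materialise a cropped mask onto the full grid.
fullMask <- function(cm, gridDim) {
  out <- array(FALSE, gridDim)
  dm <- dim(cm$mask)
  out[cm$offset[1]:(cm$offset[1] + dm[1] - 1),
      cm$offset[2]:(cm$offset[2] + dm[2] - 1),
      cm$offset[3]:(cm$offset[3] + dm[3] - 1)] <- cm$mask
  out
}
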