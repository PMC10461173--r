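# Jonker-Volgenant style shortest-augmenting-path solver for the square
# min-cost perfect assignment problem. Returns p: p[j] = row assigned to
# column j. O(n^3), deterministic.
hungarianSolve <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1)          # index n+1 = virtual source column
  p <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedJ <- which(used)
      u[p[usedJ]] <- u[p[usedJ]] + delta
      v[usedJ] <- v[usedJ] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  p[seq_len(n)]
}

# Maximum-total-weight one-to-one assignment with zero-weight cells
# forbidden. Returns the optimal total and one optimal pair set.
maxWeightAssignment <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  if (!nr || !nc || all(w <= 0))
    return(list(pairs = matrix(integer(0), ncol = 2), total = 0))
  n <- max(nr, nc)
  maxw <- max(w)
  cost <- matrix(maxw, n, n)
  allowed <- w > 0
  sub <- matrix(maxw, nr, nc)
  sub[allowed] <- maxw - w[allowed]
  cost[seq_len(nr), seq_len(nc)] <- sub
  p <- hungarianSolve(cost)
  pairs <- cbind(p, seq_len(n))
  pairs <- pairs[pairs[, 1] <= nr & pairs[, 2] <= nc, , drop = FALSE]
  keep <- w[pairs] > 0
  pairs <- pairs[keep, , drop = FALSE]
  list(pairs = pairs, total = sum(w[pairs]))
}

#' Solve the lesion-cluster assignment problem
#'
#' One-to-one assignment of rows (scan-1 clusters) to columns (warped
#' scan-2 clusters) maximising total intersection volume, by the Munkres
#' (Hungarian) algorithm. Cells with zero overlap are forbidden: spatially
#' disjoint clusters are never paired, and rows/columns with no positive
#' overlap remain unmatched. Ties between equally optimal assignments are
#' broken by preferring smaller (row, column) pairs lexicographically.
#'
#' @param overlaps Non-negative numeric matrix of overlap volumes.
#' @return List with \code{pairs} (two-column integer matrix of assigned
#'   (row, column) pairs, ordered by row), \code{unmatchedRows},
#'   \code{unmatchedCols} and \code{total} (the assigned overlap sum).
#' @examples
#' solveAssignment(matrix(c(5, 2, 1, 3), 2))$pairs
#' @export
solveAssignment <- function(overlaps) {
  w <- as.matrix(overlaps)
  if (any(w < 0) || any(!is.finite(w)))
    validationError("overlap matrix must be finite and non-negative")
  nr <- nrow(w); nc <- ncol(w)
  best <- maxWeightAssignment(w)
  tol <- 1e-9 * max(1, best$total)
  # lexicographic refinement: fix rows in order, each to the smallest
  # feasible column that still attains the optimal total
  usedCols <- logical(nc)
  fixed <- matrix(integer(0), ncol = 2)
  fixedTotal <- 0
  for (i in seq_len(nr)) {
    rest <- if (i < nr) (i + 1L):nr else integer(0)
    chosen <- 0L
    for (j in seq_len(nc)) {
      if (usedCols[j] || w[i, j] <= 0) next
      sub <- w[rest, !usedCols & seq_len(nc) != j, drop = FALSE]
      attainable <- fixedTotal + w[i, j] + maxWeightAssignment(sub)$total
      if (attainable >= best$total - tol) { chosen <- j; break }
    }
    if (chosen) {
      fixed <- rbind(fixed, c(i, chosen))
      usedCols[chosen] <- TRUE
      fixedTotal <- fixedTotal + w[i, chosen]
    }
  }
  pairs <- fixed
  list(pairs = pairs,
       unmatchedRows = setdiff(seq_len(nr), pairs[, 1]),
       unmatchedCols = setdiff(seq_len(nc), pairs[, 2]),
       total = sum(w[pairs]))
}
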