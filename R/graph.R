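# Canonical edge bookkeeping. An edge is (scan-1 element, scan-2 element);
# the scan-1 element is a lesion index or "NEW", the scan-2 element a lesion
# index or "DISAPPEARED". For sorting, sentinels take the numeric value 0
# (matching the workbook CSV convention) so the canonical order is
# ascending by (scan-1 value, scan-2 value).

edgeSortValue <- function(x, sentinel) {
  v <- suppressWarnings(as.numeric(x))
  v[x == sentinel] <- 0
  v
}

canonicalEdges <- function(e) {
  if (is.null(e) || !length(e)) {
    m <- matrix(character(0), ncol = 2)
  } else {
    m <- matrix(as.character(e), ncol = 2)
  }
  m <- unique(m)
  o <- order(edgeSortValue(m[, 1], NEW_NODE),
             edgeSortValue(m[, 2], DISAPPEARED_NODE))
  m <- m[o, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Canonical edge keys of a match graph
#'
#' Each edge is encoded as \code{"a|b"}; two graphs are equal iff their key
#' sets are equal. Accepts a \linkS4class{MatchGraph} or a two-column edge
#' matrix.
#'
#' @param x A \linkS4class{MatchGraph} or two-column character matrix.
#' @return Character vector of edge keys.
#' @export
edgeKeys <- function(x) {
  e <- if (is(x, "MatchGraph")) x@edges else canonicalEdges(x)
  if (!nrow(e)) return(character(0))
  paste(e[, 1], e[, 2], sep = "|")
}

#' Build a bipartite match graph
#'
#' Constructs the match graph for a scan pair from the lesion index sets and
#' the set of matched pairs. Every scan-1 lesion that appears in no match
#' receives the edge \code{(index, DISAPPEARED)}; every unmatched scan-2
#' lesion receives \code{(NEW, index)}. Many-to-one and one-to-many matches
#' (splits/merges) are permitted.
#'
#' @param n1,n2 Integer vectors of lesion indices present on scan 1 / scan 2.
#' @param matches Two-column matrix (or data.frame) of matched index pairs
#'   (scan-1 index, scan-2 index); may have zero rows.
#' @return A valid \linkS4class{MatchGraph}.
#' @examples
#' g <- buildGraph(1:2, 1:2, cbind(1:2, 1:2))
#' edges(g)
#' @export
buildGraph <- function(n1, n2, matches = NULL) {
  n1 <- sort(unique(as.integer(n1)))
  n2 <- sort(unique(as.integer(n2)))
  if (any(is.na(n1)) || any(is.na(n2)))
    validationError("lesion indices must be integers")
  if (is.null(matches) || !length(matches)) {
    m <- matrix(integer(0), ncol = 2)
  } else {
    m <- as.matrix(matches)
    storage.mode(m) <- "integer"
    if (ncol(m) != 2L)
      validationError("matches must have two columns")
  }
  bad1 <- setdiff(m[, 1], n1)
  if (length(bad1))
    validationError("match references unknown scan-1 index: %s",
                    paste(bad1, collapse = ", "))
  bad2 <- setdiff(m[, 2], n2)
  if (length(bad2))
    validationError("match references unknown scan-2 index: %s",
                    paste(bad2, collapse = ", "))
  e <- cbind(as.character(m[, 1]), as.character(m[, 2]))
  un1 <- setdiff(n1, m[, 1])
  if (length(un1)) e <- rbind(e, cbind(as.character(un1), DISAPPEARED_NODE))
  un2 <- setdiff(n2, m[, 2])
  if (length(un2)) e <- rbind(e, cbind(NEW_NODE, as.character(un2)))
  new("MatchGraph", n1 = n1, n2 = n2, edges = canonicalEdges(e))
}

#' Assemble a MatchGraph from raw parts (no invariant enforcement)
#'
#' Low-level constructor used by readers and by tests that need to inspect
#' invalid graphs with \code{\link{validateGraph}}. Edges are canonicalised
#' (de-duplicated, sorted) but semantic invariants are not enforced.
#'
#' @param n1,n2 Integer index vectors.
#' @param edges Two-column character matrix of edges.
#' @return A \linkS4class{MatchGraph} (possibly semantically invalid).
#' @export
matchGraph <- function(n1, n2, edges) {
  new("MatchGraph", n1 = sort(unique(as.integer(n1))),
      n2 = sort(unique(as.integer(n2))),
      edges = canonicalEdges(edges))
}

#' @rdname MatchGraph-class
#' @export
setMethod("edges", "MatchGraph", function(x) x@edges)

#' @rdname MatchGraph-class
#' @export
setMethod("nodes1", "MatchGraph", function(x) x@n1)

#' @rdname MatchGraph-class
#' @export
setMethod("nodes2", "MatchGraph", function(x) x@n2)

#' @rdname MatchGraph-class
#' @export
setMethod("show", "MatchGraph", function(object) {
  e <- object@edges
  real <- sum(e[, 1] != NEW_NODE & e[, 2] != DISAPPEARED_NODE)
  cat(sprintf(paste0("MatchGraph: %d scan-1 lesions, %d scan-2 lesions; ",
                     "%d match edge%s, %d disappeared, %d new\n"),
              length(object@n1), length(object@n2), real,
              if (real == 1L) "" else "s",
              sum(e[, 2] == DISAPPEARED_NODE & e[, 1] != NEW_NODE),
              sum(e[, 1] == NEW_NODE & e[, 2] != DISAPPEARED_NODE)))
})

#' Check match-graph invariants
#'
#' Returns violations as data rather than raising: the empty character
#' vector means the graph is valid. Checked invariants: no
#' (NEW, DISAPPEARED) edge; every edge endpoint is a known lesion index or
#' sentinel; every real lesion node has at least one incident edge; a node
#' has a sentinel edge iff it has no edge to a real node (matched xor
#' new/disappeared).
#'
#' @param g A \linkS4class{MatchGraph}.
#' @return Character vector of human-readable violations (empty if valid).
#' @export
validateGraph <- function(g) {
  out <- character(0)
  e <- g@edges
  a <- e[, 1]; b <- e[, 2]
  if (any(a == NEW_NODE & b == DISAPPEARED_NODE))
    out <- c(out, "edge (NEW, DISAPPEARED) is forbidden")
  known1 <- c(as.character(g@n1), NEW_NODE)
  known2 <- c(as.character(g@n2), DISAPPEARED_NODE)
  for (x in setdiff(a, known1))
    out <- c(out, sprintf("edge references unknown scan-1 element '%s'", x))
  for (x in setdiff(b, known2))
    out <- c(out, sprintf("edge references unknown scan-2 element '%s'", x))
  for (i in g@n1) {
    hit <- a == as.character(i)
    if (!any(hit)) {
      out <- c(out, sprintf("scan-1 lesion %d has no incident edge", i))
    } else {
      realE <- any(hit & b != DISAPPEARED_NODE)
      sentE <- any(hit & b == DISAPPEARED_NODE)
      if (realE && sentE)
        out <- c(out, sprintf(
          "scan-1 lesion %d is both matched and disappeared", i))
    }
  }
  for (j in g@n2) {
    hit <- b == as.character(j)
    if (!any(hit)) {
      out <- c(out, sprintf("scan-2 lesion %d has no incident edge", j))
    } else {
      realE <- any(hit & a != NEW_NODE)
      sentE <- any(hit & a == NEW_NODE)
      if (realE && sentE)
        out <- c(out, sprintf(
          "scan-2 lesion %d is both matched and new", j))
    }
  }
  out
}

#' Decompose a graph into matches and sentinel assignments
#'
#' Inverse of \code{\link{buildGraph}}: returns the real match pairs and the
#' index sets flagged disappeared/new.
#'
#' @param g A \linkS4class{MatchGraph}.
#' @return List with \code{matches} (two-column integer matrix),
#'   \code{disappeared} and \code{new} (integer vectors).
#' @export
graphParts <- function(g) {
  e <- g@edges
  real <- e[, 1] != NEW_NODE & e[, 2] != DISAPPEARED_NODE
  m <- cbind(as.integer(e[real, 1]), as.integer(e[real, 2]))
  list(matches = m,
       disappeared = as.integer(e[e[, 2] == DISAPPEARED_NODE &
                                    e[, 1] != NEW_NODE, 1]),
       new = as.integer(e[e[, 1] == NEW_NODE &
                            e[, 2] != DISAPPEARED_NODE, 2]))
}

#' Restrict a match graph to subsets of its nodes
#'
#' Keeps the given lesion indices, drops edges touching removed lesions, and
#' re-attaches sentinel edges to kept lesions that lose all their real
#' matches. Used to apply the analysis volume threshold to a reference
#' (ground-truth or reader) graph so it can be compared against a filtered
#' automated graph.
#'
#' @param g A \linkS4class{MatchGraph}.
#' @param keep1,keep2 Integer vectors of lesion indices to retain.
#' @return A valid \linkS4class{MatchGraph} over the kept nodes.
#' @export
restrictGraph <- function(g, keep1, keep2) {
  keep1 <- intersect(g@n1, as.integer(keep1))
  keep2 <- intersect(g@n2, as.integer(keep2))
  p <- graphParts(g)
  m <- p$matches
  if (nrow(m))
    m <- m[m[, 1] %in% keep1 & m[, 2] %in% keep2, , drop = FALSE]
  buildGraph(keep1, keep2, m)
}

#' Test two match graphs for equality
#'
#' Node sets and canonical edge sets must both be equal.
#'
#' @param a,b \linkS4class{MatchGraph} objects.
#' @return Logical scalar.
#' @export
graphEqual <- function(a, b) {
  identical(a@n1, b@n1) && identical(a@n2, b@n2) &&
    setequal(edgeKeys(a), edgeKeys(b)) &&
    length(edgeKeys(a)) == length(edgeKeys(b))
}
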