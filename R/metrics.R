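asKeys <- function(x) {
  if (is(x, "MatchGraph")) return(edgeKeys(x))
  if (is.character(x) && is.null(dim(x))) return(unique(x))
  edgeKeys(x)
}

#' Agreement metrics between two edge sets
#'
#' All four metrics of match-graph agreement, over full edge sets with
#' sentinel edges counting as ordinary edges. With edge sets \eqn{E_A} and
#' \eqn{E_B}: precision \eqn{|E_A \cap E_B| / |E_A|}, recall
#' \eqn{|E_A \cap E_B| / |E_B|}, F1 the harmonic mean of the two
#' (equivalently \eqn{2|E_A \cap E_B| / (2|E_A \cap E_B| + |E_A
#' \setminus E_B| + |E_B \setminus E_A|)}), and the number of differences
#' \eqn{N_d = |E_A \setminus E_B| + |E_B \setminus E_A|} (the symmetric
#' difference). F1 and \eqn{N_d} are symmetric in their arguments;
#' precision and recall swap under argument reversal. When an edge set is
#' empty the affected ratio is conventionally 1 (flagged in
#' \code{\link{compareGraphs}} reports).
#'
#' @param eA,eB Edge sets: \linkS4class{MatchGraph}s, two-column edge
#'   matrices, or canonical key vectors (see \code{\link{edgeKeys}}).
#' @return A fraction in [0, 1], or a non-negative integer for
#'   \code{numDifferences}.
#' @examples
#' edgePrecision(c("1|1", "2|2", "3|DISAPPEARED"),
#'               c("1|1", "2|6", "3|DISAPPEARED"))
#' @export
edgePrecision <- function(eA, eB) {
  a <- asKeys(eA); b <- asKeys(eB)
  if (!length(a)) return(1)
  length(intersect(a, b)) / length(a)
}

#' @rdname edgePrecision
#' @export
edgeRecall <- function(eA, eB) {
  a <- asKeys(eA); b <- asKeys(eB)
  if (!length(b)) return(1)
  length(intersect(a, b)) / length(b)
}

#' @rdname edgePrecision
#' @export
edgeF1 <- function(eA, eB) {
  a <- asKeys(eA); b <- asKeys(eB)
  if (!length(a) && !length(b)) return(1)
  tp <- length(intersect(a, b))
  2 * tp / (2 * tp + length(setdiff(a, b)) + length(setdiff(b, a)))
}

#' @rdname edgePrecision
#' @export
numDifferences <- function(eA, eB) {
  a <- asKeys(eA); b <- asKeys(eB)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Compare two match graphs over identical node sets
#'
#' Computes the \linkS4class{MetricsReport} for an ordered pair of graphs:
#' with \code{gA} the evaluated graph (automated method, or reader A) and
#' \code{gB} the reference (reader consensus, or reader B). The node sets
#' must be identical; only the edge sets may differ.
#'
#' @param gA,gB \linkS4class{MatchGraph}s sharing \code{n1} and \code{n2}.
#' @return A \linkS4class{MetricsReport}.
#' @export
compareGraphs <- function(gA, gB) {
  d1 <- c(setdiff(gA@n1, gB@n1), setdiff(gB@n1, gA@n1))
  d2 <- c(setdiff(gA@n2, gB@n2), setdiff(gB@n2, gA@n2))
  if (length(d1) || length(d2))
    validationError(
      "graphs have different node sets (scan 1: %s; scan 2: %s)",
      if (length(d1)) paste(sort(d1), collapse = ",") else "-",
      if (length(d2)) paste(sort(d2), collapse = ",") else "-")
  a <- edgeKeys(gA); b <- edgeKeys(gB)
  flags <- c(if (!length(a)) "empty_e_a", if (!length(b)) "empty_e_b")
  new("MetricsReport", precision = edgePrecision(a, b),
      recall = edgeRecall(a, b), f1 = edgeF1(a, b),
      nDifferences = as.integer(numDifferences(a, b)),
      flags = as.character(flags))
}

#' @rdname MetricsReport-class
#' @param object A \linkS4class{MetricsReport}.
#' @export
setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("precision %.4f, recall %.4f, F1 %.4f, N_d %d%s\n",
              object@precision, object@recall, object@f1,
              object@nDifferences,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' Convert a metrics report to a plain list / JSON
#'
#' @param report A \linkS4class{MetricsReport}.
#' @return Named list with elements \code{precision}, \code{recall},
#'   \code{f1}, \code{n_differences}, \code{flags}.
#' @export
metricsAsList <- function(report) {
  list(precision = report@precision, recall = report@recall,
       f1 = report@f1, n_differences = report@nDifferences,
       flags = as.list(report@flags))
}
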