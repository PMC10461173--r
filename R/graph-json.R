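#' Read and write match graphs as JSON
#'
#' Schema: \code{{"n1": [ints], "n2": [ints], "edges": [[a, b], ...]}} with
#' sentinel nodes encoded as the strings \code{"NEW"} and
#' \code{"DISAPPEARED"} and edges in stable canonical order, so identical
#' graphs serialise to byte-identical files.
#'
#' @param g A \linkS4class{MatchGraph}.
#' @param path File path.
#' @return \code{writeGraphJSON} returns \code{path} invisibly;
#'   \code{readGraphJSON} returns a \linkS4class{MatchGraph}.
#' @export
writeGraphJSON <- function(g, path) {
  e <- g@edges
  edgeList <- lapply(seq_len(nrow(e)), function(i) {
    lapply(1:2, function(k) {
      v <- e[i, k]
      if (v %in% c(NEW_NODE, DISAPPEARED_NODE)) v else as.integer(v)
    })
  })
  obj <- list(n1 = as.integer(g@n1), n2 = as.integer(g@n2), edges = edgeList)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "list")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeGraphJSON
#' @export
readGraphJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("n1", "n2", "edges"))
    if (is.null(obj[[f]]))
      formatError("graph JSON is missing field '%s'", f)
  e <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(p) {
      if (length(p) != 2L)
        formatError("graph JSON edge is not a pair")
      c(as.character(p[[1]]), as.character(p[[2]]))
    }))
  } else {
    matrix(character(0), ncol = 2)
  }
  g <- matchGraph(unlist(obj$n1), unlist(obj$n2), e)
  v <- validateGraph(g)
  if (length(v))
    validationError("graph JSON violates invariants: %s",
                    paste(v, collapse = "; "))
  g
}
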