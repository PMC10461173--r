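#' Read a reader-workbook match table
#'
#' Parses the two-column CSV dialect used by reader workbooks: each row
#' records one correspondence, with a lesion index in each column for a
#' match and a zero in the column of the scan where the lesion is absent
#' (disappeared or new). An optional header row is auto-detected (a first
#' row with any non-numeric field is treated as a header). Lesions listed in
#' \code{n1}/\code{n2} but mentioned in no row are auto-completed with their
#' sentinel edge, with a warning naming the indices. Duplicate identical
#' rows are collapsed with a warning. A (0, 0) row is a format error;
#' indices outside \code{n1}/\code{n2} are validation errors.
#'
#' @param path CSV file path.
#' @param n1,n2 Integer vectors enumerating the lesions present on each
#'   scan.
#' @return A valid \linkS4class{MatchGraph}.
#' @export
readMatchTable <- function(path, n1, n2) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(buildGraph(n1, n2, NULL))
  first <- strsplit(lines[[1]], ",")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(trimws(first)))))
  tab <- utils::read.csv(textConnection(paste(lines, collapse = "\n")),
                         header = hasHeader)
  if (ncol(tab) < 2L)
    formatError("match table must have two columns")
  a <- suppressWarnings(as.numeric(tab[[1]]))
  b <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(a)) || any(is.na(b)))
    formatError("match table contains non-numeric entries")
  if (any(a != round(a)) || any(b != round(b)) || any(a < 0) || any(b < 0))
    formatError("match table entries must be non-negative integers")
  a <- as.integer(a); b <- as.integer(b)
  if (any(a == 0L & b == 0L))
    formatError("match table row with zero in both columns")
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    warning("duplicate match-table rows collapsed: ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  n1 <- sort(unique(as.integer(n1)))
  n2 <- sort(unique(as.integer(n2)))
  bad1 <- setdiff(a[a > 0L], n1)
  if (length(bad1))
    validationError("match table references unknown scan-1 index: %s",
                    paste(sort(bad1), collapse = ", "))
  bad2 <- setdiff(b[b > 0L], n2)
  if (length(bad2))
    validationError("match table references unknown scan-2 index: %s",
                    paste(sort(bad2), collapse = ", "))
  e1 <- ifelse(a == 0L, NEW_NODE, as.character(a))
  e2 <- ifelse(b == 0L, DISAPPEARED_NODE, as.character(b))
  miss1 <- setdiff(n1, a)
  miss2 <- setdiff(n2, b)
  if (length(miss1) || length(miss2)) {
    warning("lesions absent from the match table auto-completed with ",
            "sentinel edges: ",
            paste(c(if (length(miss1))
                      paste0("scan 1: ", paste(miss1, collapse = ",")),
                    if (length(miss2))
                      paste0("scan 2: ", paste(miss2, collapse = ","))),
                  collapse = "; "))
    e1 <- c(e1, as.character(miss1), rep(NEW_NODE, length(miss2)))
    e2 <- c(e2, rep(DISAPPEARED_NODE, length(miss1)), as.character(miss2))
  }
  g <- matchGraph(n1, n2, cbind(e1, e2))
  v <- validateGraph(g)
  if (length(v))
    validationError("match table violates graph invariants: %s",
                    paste(v, collapse = "; "))
  g
}

#' Write a match graph as a reader-workbook table
#'
#' Inverse of \code{\link{readMatchTable}}: sentinels become zeros, rows are
#' sorted ascending by (scan-1 entry, scan-2 entry), and a
#' \code{scan1,scan2} header is written.
#'
#' @param g A \linkS4class{MatchGraph}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatchTable <- function(g, path) {
  e <- g@edges
  a <- ifelse(e[, 1] == NEW_NODE, 0L, suppressWarnings(as.integer(e[, 1])))
  b <- ifelse(e[, 2] == DISAPPEARED_NODE, 0L,
              suppressWarnings(as.integer(e[, 2])))
  o <- order(a, b)
  utils::write.csv(data.frame(scan1 = a[o], scan2 = b[o]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
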