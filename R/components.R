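connectivityOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1,
                 validationError("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Connected-component labelling of a binary mask
#'
#' Assigns each connected foreground component a unique positive integer,
#' in deterministic raster-scan order of the component's first-encountered
#' voxel (column-major order of the array), so repeated runs yield
#' identical label maps.
#'
#' @param mask A binary \linkS4class{LabelVolume} (any positive value is
#'   foreground).
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners; the default).
#' @return A \linkS4class{LabelVolume} of component indices.
#' @examples
#' m <- array(0L, c(5, 5, 1)); m[1, 1, 1] <- 1L; m[4, 4, 1] <- 1L
#' labelValues(labelComponents(labelVolume(m)))
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask@voxels)
  fg <- which(mask@voxels > 0L)
  out <- integer(prod(d))
  if (length(fg)) {
    offs <- connectivityOffsets(connectivity)
    # keep only one direction per offset pair; undirected edges
    offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                   (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
                 drop = FALSE]
    rank <- integer(prod(d))
    rank[fg] <- seq_along(fg)
    ijk <- arrayInd(fg, d)
    ee <- vector("list", nrow(offs))
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      nb <- sweep(ijk, 2L, o, "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) +
        d[1] * d[2] * (nb[ok, 3] - 1L)
      hit <- rank[lin] > 0L
      ee[[r]] <- cbind(rank[fg[ok]][hit], rank[lin][hit])
    }
    ee <- do.call(rbind, ee)
    gr <- igraph::graph_from_edgelist(
      rbind(ee, cbind(seq_along(fg), seq_along(fg))), directed = FALSE)
    memb <- igraph::components(gr)$membership[seq_along(fg)]
    # relabel so component 1 contains the first voxel in raster order
    firstVox <- tapply(seq_along(fg), memb, min)
    newId <- integer(max(memb))
    newId[as.integer(names(firstVox))[order(firstVox)]] <-
      seq_along(firstVox)
    out[fg] <- newId[memb]
  }
  labelVolume(array(out, d), mask@spacing, mask@origin, mask@direction)
}
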