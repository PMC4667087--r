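#' Label connected components of a 3-D binary mask
#'
#' Labels the foreground voxels of a 3-D logical array into connected
#' components under 6-, 18- or 26-connectivity. Adjacency is resolved by
#' matching shifted linear indices and components are extracted from the
#' resulting voxel adjacency graph.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return Integer array of `dim(mask)`: 0 for background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  dm <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dm)
  if (length(idx) == 0L) return(lab)

  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs$ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = offs$ord == 1, "18" = offs$ord %in% 1:2,
                 "26" = offs$ord >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  offs <- offs[keep, , drop = FALSE]
  # half the offsets suffice for an undirected adjacency
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), , drop = FALSE]

  co <- arrayInd(idx, dm)
  node_of <- integer(prod(dm))           # linear voxel index -> node id
  node_of[idx] <- seq_along(idx)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs$dx[k]; ny <- co[, 2] + offs$dy[k]; nz <- co[, 3] + offs$dz[k]
    ok <- nx >= 1 & nx <= dm[1] & ny >= 1 & ny <= dm[2] & nz >= 1 & nz <= dm[3]
    nl <- (nz[ok] - 1L) * dm[1] * dm[2] + (ny[ok] - 1L) * dm[1] + nx[ok]
    tgt <- node_of[nl]
    src <- which(ok)[tgt > 0L]
    edges[[k]] <- cbind(src, tgt[tgt > 0L])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # relabel so component 1 is the largest
  ord <- order(comp$csize, decreasing = TRUE)
  relab <- integer(comp$no); relab[ord] <- seq_len(comp$no)
  lab[idx] <- relab[comp$membership]
  lab
}

# Remove 26-connected components smaller than min_voxels from a binary mask.
prune_small_components <- function(mask, min_voxels) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, 26)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}
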