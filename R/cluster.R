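#' Threshold a statistic map and label 26-connected clusters
#'
#' Voxels strictly exceeding the threshold are partitioned into 26-connected
#' components. Per cluster the size, peak value and peak mm coordinate are
#' reported, along with the global peak; peak ties are broken by the first
#' voxel in ascending linear index order, so the output is deterministic.
#'
#' @param stat_array 3D numeric array of statistics (`NA` = not analyzed).
#' @param threshold Critical value; cluster membership requires
#'   `stat > threshold`.
#' @param affine 4x4 voxel-to-mm affine (0-based indices); `NULL` reports
#'   voxel indices as coordinates.
#' @return List with `clusters` (data.frame: `cluster`, `size`, `peak_stat`,
#'   `peak_x/y/z` in mm, ordered by decreasing size), `peak` (list: `stat`,
#'   `mm`, `ijk` 0-based) or `NULL` when nothing survives, and
#'   `n_suprathreshold`.
#' @export
threshold_and_cluster <- function(stat_array, threshold, affine = NULL) {
  stopifnot(length(dim(stat_array)) == 3L)
  d <- dim(stat_array)
  supra <- which(!is.na(stat_array) & stat_array > threshold)
  if (length(supra) == 0L) {
    return(list(clusters = data.frame(cluster = integer(), size = integer(),
                                      peak_stat = numeric(), peak_x = numeric(),
                                      peak_y = numeric(), peak_z = numeric()),
                peak = NULL, n_suprathreshold = 0L))
  }
  membership <- label_components_26(supra, d)
  vals <- stat_array[supra]
  coord_of <- function(lin) {
    ijk0 <- arrayInd(lin, d) - 1L
    if (is.null(affine)) ijk0 else voxel_to_mm(ijk0, affine)
  }
  ## per-cluster peak: max value, ties -> lowest linear index
  cl_ids <- sort(unique(membership))
  rows <- lapply(cl_ids, function(cl) {
    sel <- membership == cl
    v <- vals[sel]; lin <- supra[sel]
    best <- which(v == max(v))
    pk <- lin[best[which.min(lin[best])]]
    mm <- coord_of(pk)
    data.frame(cluster = cl, size = sum(sel), peak_stat = max(v),
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3])
  })
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(-clusters$size, clusters$cluster), , drop = FALSE]
  clusters$cluster <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL
  gbest <- which(vals == max(vals))
  gpk <- supra[gbest[which.min(supra[gbest])]]
  peak <- list(stat = max(vals),
               mm = as.numeric(coord_of(gpk)),
               ijk = as.integer(arrayInd(gpk, d) - 1L))
  list(clusters = clusters, peak = peak, n_suprathreshold = length(supra))
}

## 26-connected component labels for a set of linear voxel indices.
## Builds the neighbour edge list by shifting coordinates along the 13
## half-neighbourhood offsets and takes connected components via igraph.
label_components_26 <- function(lin_idx, d) {
  nv <- length(lin_idx)
  if (nv == 1L) return(1L)
  rank_of <- integer(prod(d))
  rank_of[lin_idx] <- seq_len(nv)
  coords <- arrayInd(lin_idx, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  half <- offs[offs[, 1L] > 0L |
                 (offs[, 1L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 1L] == 0L & offs[, 2L] == 0L & offs[, 3L] > 0L), ,
               drop = FALSE]
  edges <- vector("list", nrow(half))
  for (h in seq_len(nrow(half))) {
    nb <- sweep(coords, 2L, half[h, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 1L]) + (nb[ok, 2L] - 1L) * d[1] +
      (nb[ok, 3L] - 1L) * d[1] * d[2]
    to <- rank_of[nb_lin]
    present <- to > 0L
    if (any(present))
      edges[[h]] <- cbind(which(ok)[present], to[present])
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) return(seq_len(nv))   # all voxels isolated
  g <- igraph::graph_from_edgelist(
    matrix(as.numeric(el), ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}
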