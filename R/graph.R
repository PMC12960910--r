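#' Build an exact K-nearest-neighbour graph over units
#'
#' Directed KNN under Euclidean distance, either in 2-D coordinate space
#' (`mode = "spatial"`, for spatial-domain delineation) or in preprocessed
#' feature space (`mode = "feature"`, for cell-type identification without
#' reliable spatial structure). Neighbours are exact; distance ties break by
#' lower unit index so graphs are reproducible.
#'
#' @param ds a [spatial_dataset()], or a numeric matrix of points (rows =
#'   units) used directly as the metric space.
#' @param k number of neighbours per unit, `1 <= k < n`.
#' @param mode `"spatial"` (coordinates) or `"feature"` (expression matrix).
#' @return an object of class `"neighbor_graph"`: `n_units`, `k`,
#'   `neighbor_index` (`n x k` integer matrix, row `i` the neighbours of unit
#'   `i`, self excluded), `metric`.
#' @export
build_knn_graph <- function(ds, k, mode = c("spatial", "feature")) {
  mode <- match.arg(mode)
  P <- if (inherits(ds, "spatial_dataset")) {
    if (mode == "spatial") ds$coords else ds$X
  } else as.matrix(ds)
  n <- nrow(P)
  if (k < 1L) stopf("k must be >= 1")
  if (k >= n) stopf("k (%d) must be < number of units (%d)", k, n)
  nn <- exact_knn(P, k)
  structure(list(n_units = n, k = as.integer(k), neighbor_index = nn,
                 metric = paste0(mode, "_euclidean")),
            class = "neighbor_graph")
}

## Exact KNN by blocked all-pairs distances; ties broken by lower index.
exact_knn <- function(P, k) {
  n <- nrow(P)
  sq <- rowSums(P^2)
  nn <- matrix(0L, n, k)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (start in seq(1L, n, by = block)) {
    ix <- start:min(start + block - 1L, n)
    # squared distances block x n
    D <- outer(sq[ix], sq, "+") - 2 * P[ix, , drop = FALSE] %*% t(P)
    D[cbind(seq_along(ix), ix)] <- Inf      # exclude self
    for (r in seq_along(ix)) {
      o <- order(D[r, ], seq_len(n))
      nn[ix[r], ] <- o[seq_len(k)]
    }
  }
  nn
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d units, k = %d, metric = %s\n",
              x$n_units, x$k, x$metric))
  invisible(x)
}

#' Edge list of a neighbour graph
#'
#' @param g a `"neighbor_graph"`.
#' @return integer matrix with columns `source` (the neighbour), `target`
#'   (the unit it is a neighbour of) and `rank` (1 = nearest).
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  n <- g$n_units; k <- g$k
  cbind(source = as.integer(g$neighbor_index),
        target = rep(seq_len(n), times = k),
        rank = rep(seq_len(k), each = n))
}

#' Export a neighbour graph as an edge-list TSV
#' @param g a `"neighbor_graph"`.
#' @param path output file.
#' @export
export_edges_tsv <- function(g, path) {
  utils::write.table(as.data.frame(graph_edges(g)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition units into mini-batches with neighbourhood closure
#'
#' A seeded shuffle assigns every unit to exactly one batch as a *target*;
#' each batch additionally carries every target's full neighbour list
#' (*members* = targets plus neighbours, de-duplicated, targets first), so a
#' single-hop graph encoder sees complete neighbourhoods for all targets.
#' Neighbour units may repeat across batches.
#'
#' @param g a `"neighbor_graph"`.
#' @param batch_size number of targets per batch.
#' @param seed integer seed for the shuffle.
#' @return list of `"mini_batch"` objects with elements `target_ids`,
#'   `member_ids`, `target_pos` (positions of targets within members) and
#'   `local_edges` (integer matrix `src`/`dst` in member-local positions; all
#'   graph edges with both endpoints among members).
#' @export
make_batches <- function(g, batch_size, seed = 0L) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  n <- g$n_units
  perm <- with_seed(seed, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    targets <- sort(perm[s:min(s + batch_size - 1L, n)])
    nbrs <- unique(as.integer(g$neighbor_index[targets, , drop = FALSE]))
    members <- c(targets, setdiff(nbrs, targets))
    pos <- integer(n); pos[members] <- seq_along(members)
    # all graph edges (neighbor -> unit) internal to the member set
    dst_all <- rep(members, times = g$k)
    src_all <- as.integer(g$neighbor_index[members, , drop = FALSE])
    keep <- pos[src_all] > 0L
    structure(list(
      target_ids = targets,
      member_ids = members,
      target_pos = seq_along(targets),
      local_edges = cbind(src = pos[src_all[keep]], dst = pos[dst_all[keep]]),
      local_X = NULL),
      class = "mini_batch")
  })
}
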