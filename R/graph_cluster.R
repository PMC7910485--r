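# exact k-nearest neighbours of `query` rows among `ref` rows, chunked so no
# n x n matrix is held for large inputs; ties broken by lower ref index
# (order() is stable). `exclude_self` skips ref row equal to the query row id.
.knn_index <- function(ref, query = NULL, k, exclude_self = is.null(query),
                       chunk = 1024L) {
  force(exclude_self) # must see `query` before it is defaulted to `ref`
  if (is.null(query)) query <- ref
  nr <- nrow(ref); nq <- nrow(query)
  if (k > nr - as.integer(exclude_self)) stop("k too large for reference size")
  idx <- matrix(0L, nq, k)
  dmat <- matrix(0, nq, k)
  rs_ref <- rowSums(ref^2)
  for (from in seq(1, nq, by = chunk)) {
    to <- min(from + chunk - 1L, nq)
    q <- query[from:to, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rs_ref, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (ii in seq_len(nrow(d2))) {
      row <- d2[ii, ]
      gi <- from + ii - 1L
      if (exclude_self) row[gi] <- Inf
      ord <- order(row)[seq_len(k)]
      idx[gi, ] <- ord
      dmat[gi, ] <- sqrt(row[ord])
    }
  }
  list(index = idx, dist = dmat)
}

#' Exact K-nearest-neighbor graph of an embedding
#'
#' Neighbors are found by exact Euclidean distance (no approximation), with
#' ties broken toward the lower cell index. With `symmetrize = TRUE` the
#' directed KNN relation is symmetrized by union, so every node ends up with
#' at least `k` incident edges.
#'
#' @param U Embedding matrix (cells x dims).
#' @param k Neighbors per node, `< n`.
#' @param symmetrize Symmetrize the adjacency by union.
#' @return A `knn_graph`: list with `adjacency` (sparse 0/1 matrix),
#'   `neighbors` (n x k index matrix), `dist` (n x k distances), `k`.
#' @export
knn_graph <- function(U, k = 15, symmetrize = TRUE) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- .knn_index(U, k = k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$index),
                            x = 1, dims = c(n, n))
  if (symmetrize) {
    A <- A + Matrix::t(A)
    A@x[] <- 1
  }
  structure(list(adjacency = Matrix::drop0(A), neighbors = nn$index,
                 dist = nn$dist, k = k, n_nodes = n),
            class = "knn_graph")
}

# coerce the accepted graph representations to a sparse adjacency
.as_adjacency <- function(graph) {
  if (inherits(graph, "knn_graph")) return(graph$adjacency)
  if (inherits(graph, "ensemble_graph")) return(graph$combined)
  if (is(graph, "sparseMatrix") || is.matrix(graph)) return(graph)
  stop("unsupported graph representation")
}

#' Graph community detection
#'
#' Pluggable community detection on a (weighted) cell-cell graph: Louvain by
#' default, Leiden optionally. Deterministic given `seed`. Labels are
#' contiguous integers starting at 0.
#'
#' @param graph A `knn_graph`, `ensemble_graph`, or (sparse) adjacency
#'   matrix; edge weights are used.
#' @param resolution Resolution parameter of the community algorithm.
#' @param seed Integer seed.
#' @param method `"louvain"` (default) or `"leiden"`.
#' @return Integer vector of 0-based cluster labels.
#' @export
cluster_graph <- function(graph, resolution = 1, seed = 1, method = c("louvain", "leiden")) {
  method <- match.arg(method)
  A <- .as_adjacency(graph)
  if (nrow(A) == 0 || sum(A) == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "max", weighted = TRUE,
                                           diag = FALSE)
  set.seed(seed)
  comm <- switch(method,
    louvain = igraph::cluster_louvain(g, resolution = resolution),
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    resolution = resolution))
  mem <- igraph::membership(comm)
  as.integer(match(mem, sort(unique(mem))) - 1L)
}

#' Cluster connectivity index
#'
#' For each cell, its `K` nearest neighbors (exact Euclidean, ascending) are
#' checked against the cell's cluster label; each `i`-th neighbor with a
#' different label adds `1/i`. The total over all cells is 0 when every
#' neighborhood is label-pure and grows as clusters blur into each other, so
#' lower is better.
#'
#' @param U Embedding matrix (cells x dims).
#' @param labels Cluster label per cell.
#' @param K Neighbors examined per cell.
#' @return List with `total` (the index) and `mean` (per-cell average).
#' @export
connectivity_index <- function(U, labels, K = 15) {
  U <- as.matrix(U)
  n <- nrow(U)
  stopifnot(length(labels) == n, K < n)
  nn <- .knn_index(U, k = K)
  diff_lab <- matrix(labels[nn$index], n, K) != labels
  contrib <- diff_lab %*% (1 / seq_len(K))
  total <- sum(contrib)
  list(total = total, mean = total / n)
}

#' Coverage entropy of a 2-D embedding
#'
#' Quantifies how uniformly the highest-coverage cells spread over the
#' embedding: the top `top_fraction` cells by coverage are binned on a
#' `grid_bins x grid_bins` grid spanning the bounding box of the *whole*
#' embedding, and the Shannon entropy (nats) of the occupancy distribution is
#' returned. Depth-confounded embeddings concentrate high-coverage cells in a
#' small region and score low; well-normalized embeddings spread them over
#' the occupied space and score high. (Gridding only the selected cells'
#' own bounding box would hide exactly that concentration, so the full-box
#' convention is used.)
#'
#' @param embedding2d Two-column matrix of 2-D coordinates.
#' @param coverage Per-cell coverage.
#' @param top_fraction Fraction of cells (highest coverage) examined.
#' @param grid_bins Grid resolution per axis.
#' @return Entropy in nats.
#' @export
coverage_entropy <- function(embedding2d, coverage, top_fraction = 0.1,
                             grid_bins = 50) {
  embedding2d <- as.matrix(embedding2d)
  stopifnot(ncol(embedding2d) == 2, nrow(embedding2d) == length(coverage))
  n_sel <- max(1L, round(top_fraction * length(coverage)))
  sel <- order(coverage, decreasing = TRUE)[seq_len(n_sel)]
  if (n_sel < 10) warning("fewer than 10 high-coverage cells selected")
  bin1 <- .grid_bin(embedding2d[, 1], grid_bins)[sel]
  bin2 <- .grid_bin(embedding2d[, 2], grid_bins)[sel]
  counts <- table(factor(bin1, levels = seq_len(grid_bins)),
                  factor(bin2, levels = seq_len(grid_bins)))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

.grid_bin <- function(v, nb) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(1L, length(v)))
  pmin(floor((v - rng[1]) / diff(rng) * nb) + 1L, nb)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement corrected for chance; 1 for identical partitions
#' (up to label permutation), ~0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; 1 for identical partitions, 0 for independent ones.
#'
#' @inheritParams ari
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  2 * mi / (ha + hb)
}
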