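#' Project query cells onto a reference landmark embedding
#'
#' Mechanically identical to [nystrom_extend()]: cross Jaccard similarity of
#' each query cell to the reference landmarks, depth normalization with the
#' reference regression model, degree normalization, and mapping through the
#' landmark eigenbasis. The query matrix must be binned on the reference's
#' kept bins.
#'
#' @param model A `nystrom_model` fitted on the reference.
#' @param y A `cell_bin_matrix` (or binary matrix) of query cells over the
#'   reference bins.
#' @return A list with `U_query` (l x r) and `joint` (landmarks stacked on
#'   query rows, `(k + l) x r`).
#' @export
project_query <- function(model, y) {
  U_query <- nystrom_extend(model, y)
  list(U_query = U_query, joint = rbind(model$U_kk, U_query))
}

#' Mutual-nearest-neighbor anchors between reference and query
#'
#' A pair (reference cell `i`, query cell `c`) is an anchor when `c` is
#' among `i`'s `k_nearest` nearest query cells *and* `i` is among `c`'s
#' `k_nearest` nearest reference cells (Euclidean distance in the joint
#' embedding). Query cells without any anchor are flagged: they have no
#' counterpart in the reference and are excluded from label transfer.
#'
#' @param U_ref Reference embedding (k x r).
#' @param U_query Query embedding (l x r), same `r`.
#' @param k_nearest Neighborhood size on both sides (clamped when either
#'   side is smaller).
#' @return An `anchor_set`: list with `pairs` (data.frame ref/query index),
#'   `unanchored_query` (query indices without anchors), `k_nearest`.
#' @export
find_anchors <- function(U_ref, U_query, k_nearest = 5) {
  U_ref <- as.matrix(U_ref); U_query <- as.matrix(U_query)
  stopifnot(ncol(U_ref) == ncol(U_query))
  k_eff <- min(k_nearest, nrow(U_ref), nrow(U_query))
  ref_nn <- .knn_index(U_query, U_ref, k = k_eff, exclude_self = FALSE)$index
  query_nn <- .knn_index(U_ref, U_query, k = k_eff, exclude_self = FALSE)$index
  ref_idx <- rep(seq_len(nrow(U_ref)), k_eff)
  qry_idx <- as.vector(ref_nn)
  mutual <- vapply(seq_along(ref_idx), function(t) {
    ref_idx[t] %in% query_nn[qry_idx[t], ]
  }, logical(1))
  pairs <- data.frame(ref = ref_idx[mutual], query = qry_idx[mutual])
  pairs <- pairs[order(pairs$ref, pairs$query), , drop = FALSE]
  rownames(pairs) <- NULL
  unanchored <- setdiff(seq_len(nrow(U_query)), unique(pairs$query))
  structure(list(pairs = pairs, unanchored_query = unanchored,
                 k_nearest = k_eff),
            class = "anchor_set")
}

#' Score anchors by shared-nearest-neighbor consistency
#'
#' Each anchor is scored by how consistent the two cells' neighborhoods are
#' in the joint embedding: the number of shared members of their `snn_k`
#' nearest-neighbor sets, divided by `snn_k`. Raw scores are then rescaled
#' between their 0.01 and 0.90 quantiles and clipped to `[0, 1]`, so the
#' bulk of well-supported anchors score near 1 and isolated pairings near 0.
#'
#' @param anchors An `anchor_set`.
#' @param U_ref,U_query The embeddings used to build the anchors.
#' @param snn_k Neighborhood size of the shared-nearest-neighbor graph.
#' @return The `anchor_set` with a `scores` vector (one per pair) added.
#' @export
score_anchors <- function(anchors, U_ref, U_query, snn_k = 30) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (nrow(anchors$pairs) == 0) stop("no anchors to score")
  joint <- rbind(as.matrix(U_ref), as.matrix(U_query))
  n_ref <- nrow(U_ref)
  k_eff <- min(snn_k, nrow(joint) - 1L)
  nn <- .knn_index(joint, k = k_eff)$index
  raw <- vapply(seq_len(nrow(anchors$pairs)), function(t) {
    a <- anchors$pairs$ref[t]
    b <- n_ref + anchors$pairs$query[t]
    length(intersect(nn[a, ], nn[b, ])) / k_eff
  }, numeric(1))
  lo <- quantile(raw, 0.01); hi <- quantile(raw, 0.90)
  scores <- if (hi > lo) (raw - lo) / (hi - lo) else rep(1, length(raw))
  anchors$scores <- pmin(pmax(scores, 0), 1)
  anchors
}

#' Anchor weights for each query cell
#'
#' For each query cell `c`, its `s` nearest anchors (Euclidean distance to
#' the anchors' query-side cells) receive weights derived from distance and
#' anchor score: `D = (1 - dist(c, a_i) / dist(c, a_s)) * S_i` (zero for the
#' `s`-th anchor by construction), softened as `1 - exp(-D / (2/sd)^2)` and
#' normalized to sum to 1 across the `s` anchors. Anchors beyond the `s`-th
#' get weight 0.
#'
#' @param U_query Query embedding.
#' @param anchors A scored `anchor_set` (see [score_anchors()]).
#' @param s Anchors per query cell (clamped to the anchor count).
#' @param sd Bandwidth parameter of the exponential softening.
#' @return A `transfer_weights`: list with sparse `W`
#'   (query x anchors, rows summing to 1 for anchored queries), `anchors`,
#'   `s`.
#' @export
transfer_weights <- function(U_query, anchors, s = 50, sd = 1) {
  stopifnot(inherits(anchors, "anchor_set"), !is.null(anchors$scores))
  pairs <- anchors$pairs
  n_anchor <- nrow(pairs)
  if (n_anchor < 1) stop("need at least one anchor")
  U_query <- as.matrix(U_query)
  l <- nrow(U_query)
  s_eff <- min(s, n_anchor)
  anchor_pts <- U_query[pairs$query, , drop = FALSE]
  nn <- .knn_index(anchor_pts, U_query, k = s_eff, exclude_self = FALSE)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (c_i in seq_len(l)) {
    a_idx <- nn$index[c_i, ]
    d <- nn$dist[c_i, ]
    d_s <- d[s_eff]
    Dci <- if (d_s > 0) (1 - d / d_s) * anchors$scores[a_idx]
           else anchors$scores[a_idx] # all anchors coincide with the query
    Dt <- 1 - exp(-Dci / (2 / sd)^2)
    if (sum(Dt) <= 0) {
      warning("all softened weights zero for query ", c_i,
              "; using uniform weights over its ", s_eff, " anchors")
      Dt <- rep(1, s_eff)
    }
    w <- Dt / sum(Dt)
    keep <- w > 0
    trip_i <- c(trip_i, rep.int(c_i, sum(keep)))
    trip_j <- c(trip_j, a_idx[keep])
    trip_x <- c(trip_x, w[keep])
  }
  W <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(l, n_anchor))
  structure(list(W = W, anchors = anchors, s = s_eff, sd = sd),
            class = "transfer_weights")
}

#' Predict query labels from anchor weights
#'
#' With `L` the one-hot label matrix of the reference cells, each anchor
#' inherits its reference-side row and the query probabilities are
#' `P = W L_anchor`; rows sum to 1 for anchored queries. Queries whose best
#' probability falls below `threshold`, and queries without anchors, are
#' flagged as unassigned.
#'
#' @param weights A `transfer_weights`.
#' @param ref_labels Label per reference cell (factor, character or
#'   integer).
#' @param threshold Minimum best-label probability to accept a prediction.
#' @return A list with `P` (query x clusters probability matrix),
#'   `best_label`, `best_score`, `flagged` (logical; low confidence or no
#'   anchor).
#' @export
predict_labels <- function(weights, ref_labels, threshold = 0.9) {
  stopifnot(inherits(weights, "transfer_weights"))
  pairs <- weights$anchors$pairs
  lev <- sort(unique(ref_labels))
  L_anchor <- Matrix::sparseMatrix(
    i = seq_len(nrow(pairs)),
    j = match(ref_labels[pairs$ref], lev),
    x = 1, dims = c(nrow(pairs), length(lev)))
  P <- as.matrix(weights$W %*% L_anchor)
  colnames(P) <- as.character(lev)
  best <- max.col(P, ties.method = "first")
  best_score <- P[cbind(seq_len(nrow(P)), best)]
  flagged <- best_score < threshold
  flagged[weights$anchors$unanchored_query] <- TRUE
  list(P = P, best_label = lev[best], best_score = best_score,
       flagged = flagged)
}

#' Transfer reference coordinates to query cells
#'
#' Replaces the label matrix by arbitrary per-reference coordinates (e.g.,
#' 2-D visualization positions): each query cell receives the
#' anchor-weighted average of its anchors' reference-side coordinates, i.e.
#' a convex combination.
#'
#' @param weights A `transfer_weights`.
#' @param ref_coords Matrix of coordinates per reference cell.
#' @return Query x coordinate-dimension matrix.
#' @export
transfer_coordinates <- function(weights, ref_coords) {
  stopifnot(inherits(weights, "transfer_weights"))
  ref_coords <- as.matrix(ref_coords)
  anchor_coords <- ref_coords[weights$anchors$pairs$ref, , drop = FALSE]
  as.matrix(weights$W %*% anchor_coords)
}
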