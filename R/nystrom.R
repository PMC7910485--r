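#' Fit a landmark (Nystrom) embedding model
#'
#' Samples `k` landmark cells by inverse-density sampling, fits the depth
#' model on the landmarks, computes and normalizes their pairwise Jaccard
#' kernel, and eigendecomposes the symmetric-normalized kernel. The returned
#' model carries everything needed to project further cells onto the
#' landmark manifold with [nystrom_extend()].
#'
#' @param x A `cell_bin_matrix`.
#' @param k Number of landmarks; clamped to `n` with a warning. 10,000
#'   landmarks are a robust default at atlas scale; desk-scale analyses use
#'   proportionally fewer.
#' @param r Embedding rank, `< k`.
#' @param sample_size Cells used for the depth regression (clamped to `k`).
#' @param seed Integer seed (landmark sampling and depth model).
#'
#' @return A `nystrom_model`: list with `landmark_indices` (sorted),
#'   `U_kk` (k x r), `eigenvalues`, `landmark_row_sums` (`D_kk` diagonal),
#'   `depth_model`, `landmark_p`, `X_land` (binary landmark matrix),
#'   `kept_bins`, `r`.
#' @export
fit_landmarks <- function(x, k = 10000, r, sample_size = 2000, seed = 1) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  n <- nrow(x$X)
  if (k > n) {
    warning("k = ", k, " landmarks requested but only ", n, " cells; clamping")
    k <- n
  }
  stopifnot(r < k)
  idx <- sample_by_density(x$coverage, k, seed = seed)
  land <- list(X = x$X[idx, , drop = FALSE],
               coverage = x$coverage[idx], p = x$p[idx],
               bin_coords = x$bin_coords, bin_size = x$bin_size,
               kept_bins = x$kept_bins)
  class(land) <- "cell_bin_matrix"
  model <- fit_depth_model(land, sample_size = min(sample_size, k), seed = seed)
  J <- jaccard_matrix(land)
  E <- expected_jaccard(land$p)
  N <- normalize_jaccard(J, E, model)
  emb <- spectral_embed(N, r)
  structure(list(landmark_indices = idx,
                 U_kk = emb$U,
                 eigenvalues = emb$eigenvalues,
                 landmark_row_sums = emb$row_sums,
                 depth_model = model,
                 landmark_p = land$p,
                 X_land = land$X,
                 kept_bins = x$kept_bins,
                 r = emb$r),
            class = "nystrom_model")
}

#' @exportS3Method base::print
print.nystrom_model <- function(x, ...) {
  cat("nystrom_model:", length(x$landmark_indices), "landmarks, rank",
      x$r, "\n")
  invisible(x)
}

# core out-of-sample extension given a normalized cross-similarity matrix
.extend_kernel <- function(N_vk, U_kk, eigenvalues, landmark_row_sums,
                           eig_tol = 1e-12) {
  D_vv <- rowSums(N_vk)
  if (any(D_vv <= 0)) {
    bad <- if (!is.null(rownames(N_vk))) rownames(N_vk)[D_vv <= 0] else which(D_vv <= 0)
    stop("cell(s) with zero similarity to every landmark: ",
         paste(head(bad, 5), collapse = ", "))
  }
  A_vk <- N_vk * outer(1 / sqrt(D_vv), 1 / sqrt(landmark_row_sums))
  U_vk <- A_vk %*% U_kk
  lam <- eigenvalues
  ok <- abs(lam) > eig_tol
  U_vk[, ok] <- sweep(U_vk[, ok, drop = FALSE], 2, lam[ok], "/")
  U_vk[, !ok] <- 0 # rank guard: near-singular directions carry no signal
  U_vk
}

#' Project cells onto a landmark embedding
#'
#' Computes the cross Jaccard similarity between each new cell and all
#' landmarks, depth-normalizes it with the landmark regression model
#' (expected Jaccard from the query and landmark bin fractions, capped at
#' the model's stored quantile), degree-normalizes
#' `A_vk = D_vv^{-1/2} N_vk D_kk^{-1/2}`, and maps into the landmark
#' eigenbasis `U_vk = A_vk U_kk / Lambda_kk`. Rows are independent: batch
#' extension equals cell-at-a-time extension.
#'
#' @param model A `nystrom_model`.
#' @param x_rest A `cell_bin_matrix` (or binary matrix) over the same bins
#'   as the landmark matrix.
#' @return Matrix of embedding rows (`nrow(x_rest) x r`).
#' @export
nystrom_extend <- function(model, x_rest) {
  stopifnot(inherits(model, "nystrom_model"))
  X <- if (inherits(x_rest, "cell_bin_matrix")) x_rest$X else as(x_rest, "CsparseMatrix")
  if (nrow(X) == 0) return(matrix(0, 0, model$r))
  if (ncol(X) != ncol(model$X_land))
    stop("query bins (", ncol(X), ") do not match landmark bins (",
         ncol(model$X_land), "); bin the query on the reference kept_bins")
  J <- cross_jaccard(X, model$X_land)
  p_query <- Matrix::rowSums(X) / ncol(X)
  E <- expected_jaccard(p_query, model$landmark_p)
  N <- .normalize_raw(J, E, model$depth_model$beta)
  cap <- model$depth_model$cap_value
  N[N > cap] <- cap
  U_vk <- .extend_kernel(N, model$U_kk, model$eigenvalues,
                         model$landmark_row_sums)
  rownames(U_vk) <- rownames(X)
  U_vk
}

#' Landmark embedding of a precomputed kernel matrix
#'
#' Kernel-level variant of the landmark pipeline for a similarity matrix
#' that is already normalized: eigendecomposes the landmark principal
#' submatrix after symmetric degree normalization and extends the remaining
#' rows through the landmark eigenbasis. Useful for analysing the
#' approximation itself (e.g., against a full eigendecomposition) without
#' the Jaccard/depth machinery.
#'
#' @param N Symmetric non-negative similarity matrix (n x n).
#' @param landmark_idx Indices of the landmark rows/columns.
#' @param r Embedding rank, `< length(landmark_idx)`.
#' @return A list with `U_tilde` (n x r, original row order), `U_kk`,
#'   `eigenvalues`, `landmark_idx`.
#' @export
nystrom_kernel_embed <- function(N, landmark_idx, r) {
  landmark_idx <- sort(unique(as.integer(landmark_idx)))
  stopifnot(r < length(landmark_idx))
  emb <- spectral_embed(N[landmark_idx, landmark_idx, drop = FALSE], r)
  n <- nrow(N)
  rest <- setdiff(seq_len(n), landmark_idx)
  U <- matrix(0, n, r)
  U[landmark_idx, ] <- emb$U
  if (length(rest)) {
    N_vk <- N[rest, landmark_idx, drop = FALSE]
    U[rest, ] <- .extend_kernel(N_vk, emb$U, emb$eigenvalues, emb$row_sums)
  }
  list(U_tilde = U, U_kk = emb$U, eigenvalues = emb$eigenvalues,
       landmark_idx = landmark_idx)
}

#' Landmark embedding of a full dataset
#'
#' Fits landmarks, extends all non-landmark cells, and returns the joint
#' embedding with rows restored to the original cell order (the stacked
#' (landmarks, then rest) layout is an internal detail).
#'
#' @inheritParams fit_landmarks
#' @return A list with `U` (n x r, original cell order), `model`
#'   (the `nystrom_model`), `landmark_indices`.
#' @export
nystrom_embed <- function(x, k, r, sample_size = 2000, seed = 1) {
  model <- fit_landmarks(x, k = k, r = r, sample_size = sample_size, seed = seed)
  n <- nrow(x$X)
  idx <- model$landmark_indices
  U <- matrix(0, n, model$r)
  U[idx, ] <- model$U_kk
  rest <- setdiff(seq_len(n), idx)
  if (length(rest)) {
    xr <- x$X[rest, , drop = FALSE]
    U[rest, ] <- nystrom_extend(model, xr)
  }
  rownames(U) <- rownames(x$X)
  list(U = U, model = model, landmark_indices = idx)
}

#' Ensemble of landmark embeddings as a weighted KNN graph
#'
#' Runs `p_experts` independent landmark embeddings (expert `j` uses seed
#' `seed + j`), builds a symmetrized binary KNN graph from each, and
#' averages the adjacencies with equal weights `1/p`. Edge weights of the
#' combined graph are therefore multiples of `1/p`; community detection
#' consumes them directly.
#'
#' @param x A `cell_bin_matrix`.
#' @param p_experts Number of experts (`>= 1`).
#' @param k Landmarks per expert.
#' @param r Embedding rank.
#' @param knn_k Neighbors for each expert's KNN graph.
#' @param sample_size Cells for each expert's depth regression.
#' @param seed Base seed; expert `j` uses `seed + j`.
#'
#' @return An `ensemble_graph`: list with `combined` (sparse symmetric
#'   weighted adjacency), `expert_graphs` (list of sparse binary
#'   adjacencies), `weights` (rep(1/p, p)).
#' @export
ensemble_embed <- function(x, p_experts = 5, k, r, knn_k = 15,
                           sample_size = 2000, seed = 1) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  if (p_experts < 1) stop("p_experts must be >= 1")
  n <- nrow(x$X)
  experts <- vector("list", p_experts)
  for (j in seq_len(p_experts)) {
    emb <- nystrom_embed(x, k = k, r = r, sample_size = sample_size,
                         seed = seed + j)
    g <- knn_graph(emb$U, k = knn_k, symmetrize = TRUE)
    experts[[j]] <- g$adjacency
  }
  combined <- Reduce(`+`, experts) / p_experts
  structure(list(combined = combined, expert_graphs = experts,
                 weights = rep(1 / p_experts, p_experts),
                 n_nodes = n, knn_k = knn_k),
            class = "ensemble_graph")
}
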