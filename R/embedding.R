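#' Pairwise Jaccard similarity between cells
#'
#' Computes the observed Jaccard index
#' `J_ij = |x_i & x_j| / |x_i | x_j|` between all pairs of binary rows.
#' The Jaccard index is symmetric and positivity-preserving, so it serves as
#' the kernel of the spectral embedding.
#'
#' @param x A `cell_bin_matrix`, or a binary sparse/dense matrix
#'   (cells x bins).
#' @return A dense symmetric matrix `J` with unit diagonal, attribute
#'   `kind = "observed_jaccard"`.
#' @export
jaccard_matrix <- function(x) {
  X <- if (inherits(x, "cell_bin_matrix")) x$X else as(x, "CsparseMatrix")
  cov <- Matrix::rowSums(X)
  if (any(cov == 0)) {
    bad <- rownames(X)[cov == 0]
    if (is.null(bad)) bad <- which(cov == 0)
    stop("zero-coverage cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  inter <- as.matrix(Matrix::tcrossprod(X))
  union <- outer(cov, cov, "+") - inter
  J <- inter / union
  dimnames(J) <- list(rownames(X), rownames(X))
  attr(J, "kind") <- "observed_jaccard"
  J
}

#' Cross Jaccard similarity between two sets of cells
#'
#' `J[i, j]` is the Jaccard index between row `i` of `x` and row `j` of `y`;
#' both matrices must be binary over the same bins.
#'
#' @param x,y `cell_bin_matrix` objects or binary matrices (cells x bins).
#' @return Dense `nrow(x) x nrow(y)` matrix.
#' @export
cross_jaccard <- function(x, y) {
  X <- if (inherits(x, "cell_bin_matrix")) x$X else as(x, "CsparseMatrix")
  Y <- if (inherits(y, "cell_bin_matrix")) y$X else as(y, "CsparseMatrix")
  if (ncol(X) != ncol(Y)) stop("bin sets differ between the two matrices")
  cx <- Matrix::rowSums(X); cy <- Matrix::rowSums(Y)
  if (any(cx == 0) || any(cy == 0)) stop("zero-coverage cell in cross Jaccard")
  inter <- as.matrix(Matrix::tcrossprod(X, Y))
  inter / (outer(cx, cy, "+") - inter)
}

#' Expected Jaccard similarity under random accessibility
#'
#' For two biologically unrelated cells whose "1"s are placed independently
#' with per-bin probabilities `P_i` and `P_j`, the ratio of expectations of
#' intersection over union is
#' `E_ij = P_i P_j / (P_i + P_j - P_i P_j)`.
#' `E` increases with either coverage, which is exactly the depth confounder
#' removed by [normalize_jaccard()].
#'
#' @param p Per-cell bin fractions `P_i` in `(0, 1]` (rows of the first
#'   set).
#' @param q Optional second set of bin fractions; defaults to `p`
#'   (symmetric all-pairs matrix).
#' @return Matrix `E` of expected Jaccard values, attribute
#'   `kind = "expected"`.
#' @export
expected_jaccard <- function(p, q = NULL) {
  if (any(p <= 0) || (!is.null(q) && any(q <= 0)))
    stop("expected Jaccard undefined for cells with P_i = 0")
  if (any(p > 1) || (!is.null(q) && any(q > 1)))
    stop("P_i must lie in (0, 1]")
  if (is.null(q)) q <- p
  pq <- outer(p, q)
  E <- pq / (outer(p, q, "+") - pq)
  attr(E, "kind") <- "expected"
  E
}

#' Inverse-density sampling of cells by coverage
#'
#' Samples `size` cells without replacement with probability proportional to
#' `1 / d(log10(C_i))`, where `d` is a Gaussian kernel density estimate
#' (Scott's bandwidth) over all log10 coverages. Cells in sparsely populated
#' coverage regions are therefore over-represented, preserving the coverage
#' spectrum in the subsample.
#'
#' @param coverage Per-cell fragment/bin counts `C_i`, all `> 0`.
#' @param size Number of cells to draw, `<= length(coverage)`.
#' @param seed Integer seed.
#' @return Sorted integer vector of sampled cell indices.
#' @export
sample_by_density <- function(coverage, size, seed = 1) {
  n <- length(coverage)
  if (size > n) stop("size exceeds the number of cells")
  if (any(coverage <= 0)) stop("all coverages must be positive")
  if (size == n) return(seq_len(n))
  lc <- log10(coverage)
  if (stats::sd(lc) == 0) {
    w <- rep(1, n)
  } else {
    d <- stats::density(lc, bw = "nrd", n = 512)
    dens <- stats::approx(d$x, d$y, xout = lc, rule = 2)$y
    w <- 1 / pmax(dens, .Machine$double.eps)
  }
  set.seed(seed)
  sort(sample.int(n, size = size, prob = w / sum(w)))
}

#' Fit the depth-correction regression
#'
#' Learns the relationship between observed and expected Jaccard similarity
#' on a density-sampled subset of cells by ordinary least squares of
#' `J_ij` on `(1, E_ij, E_ij^2)` over all off-diagonal pairs among the
#' sampled cells. A quadratic term captures the nonlinearity observed among
#' high-coverage cells. The 0.99 quantile of the normalized values on the
#' sampled pairs is stored as the outlier cap used by [normalize_jaccard()].
#'
#' @param x A `cell_bin_matrix`.
#' @param sample_size Number of cells used for the fit (clamped to `n`);
#'   2000 cells give estimates virtually identical to the full fit.
#' @param cap_quantile Quantile of normalized sampled pairs stored as cap.
#' @param seed Integer seed for the density sampling.
#'
#' @return A `depth_model`: list with `beta` (length-3 coefficients),
#'   `cap_value`, `sample_size`, `sampled` (indices used).
#' @export
fit_depth_model <- function(x, sample_size = 2000, cap_quantile = 0.99, seed = 1) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  n <- nrow(x$X)
  if (n < 2) stop("need at least 2 cells to fit the depth model")
  size <- min(max(sample_size, 2), n)
  idx <- sample_by_density(x$coverage, size, seed = seed)
  Xs <- x$X[idx, , drop = FALSE]
  J <- jaccard_matrix(Xs)
  E <- expected_jaccard(x$p[idx])
  off <- upper.tri(J)
  j <- J[off]; e <- E[off]
  if (stats::var(e) < .Machine$double.eps) {
    warning("degenerate expected-Jaccard values; falling back to intercept-only model")
    beta <- c(mean(j), 0, 0)
  } else {
    fit <- lm(j ~ e + I(e^2))
    beta <- unname(coef(fit))
  }
  pred <- beta[1] + beta[2] * e + beta[3] * e^2
  if (any(pred <= 0))
    stop("depth model predicts non-positive similarity for sampled pairs")
  cap_value <- unname(quantile(j / pred, cap_quantile))
  structure(list(beta = beta, cap_value = cap_value,
                 cap_quantile = cap_quantile,
                 sample_size = size, sampled = idx),
            class = "depth_model")
}

# raw normalized values without capping; shared by the full and cross paths
.normalize_raw <- function(J, E, beta) {
  pred <- beta[1] + beta[2] * E + beta[3] * E^2
  if (any(pred <= 0)) {
    bad <- which(pred <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive predicted similarity at pair (%d, %d); beta = (%.4g, %.4g, %.4g)",
      bad[1], bad[2], beta[1], beta[2], beta[3]))
  }
  J / pred
}

#' Depth-normalize an observed Jaccard matrix
#'
#' Divides each observed similarity by its depth-expected value under the
#' fitted regression, `N_ij = J_ij / (b0 + b1 E_ij + b2 E_ij^2)`, caps
#' outliers at the `cap_quantile` quantile of the off-diagonal normalized
#' values, and sets the diagonal to the maximum off-diagonal value (the
#' diagonal carries no information and would otherwise dominate the kernel).
#'
#' @param J Observed Jaccard matrix from [jaccard_matrix()].
#' @param E Expected Jaccard matrix from [expected_jaccard()].
#' @param model A `depth_model` from [fit_depth_model()].
#' @param cap_quantile Quantile used for capping (recomputed on `J`/`E`'s
#'   own off-diagonal values).
#' @return Symmetric normalized similarity matrix `N`, attribute
#'   `kind = "normalized"`.
#' @export
normalize_jaccard <- function(J, E, model, cap_quantile = 0.99) {
  stopifnot(inherits(model, "depth_model"), all(dim(J) == dim(E)))
  N <- .normalize_raw(J, E, model$beta)
  off <- row(N) != col(N)
  # quantile over unique (upper-triangle) pairs, matching fit_depth_model
  cap <- unname(quantile(N[upper.tri(N)], cap_quantile))
  N[off & N > cap] <- cap
  diag(N) <- max(N[off])
  attr(N, "kind") <- "normalized"
  N
}

#' Spectral embedding of a normalized similarity matrix
#'
#' Symmetric graph normalization `A = D^{-1/2} N D^{-1/2}` with
#' `D_ii = sum_j N_ij`, followed by eigendecomposition `A = U L U^T`. The
#' first `r` eigenvectors (descending eigenvalue) form the low-dimensional
#' manifold. Eigenvector signs are fixed so that each column's
#' largest-magnitude entry is positive.
#'
#' @param N Symmetric non-negative similarity matrix.
#' @param r Number of components to return (`< n`).
#' @return A `spectral_embedding`: list with `U` (n x r), `eigenvalues`
#'   (length r, descending), `row_sums` (the `D_ii`), `r`.
#' @export
spectral_embed <- function(N, r) {
  n <- nrow(N)
  stopifnot(r >= 1, r < n)
  D <- rowSums(N)
  if (any(D <= 0)) {
    bad <- if (!is.null(rownames(N))) rownames(N)[D <= 0] else which(D <= 0)
    stop("zero row sum for cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  s <- 1 / sqrt(D)
  A <- N * outer(s, s)
  eig <- eigen(A, symmetric = TRUE)
  U <- eig$vectors[, seq_len(r), drop = FALSE]
  U <- .fix_signs(U)
  rownames(U) <- rownames(N)
  structure(list(U = U, eigenvalues = eig$values[seq_len(r)],
                 all_eigenvalues = eig$values,
                 row_sums = D, r = r),
            class = "spectral_embedding")
}

# sign convention: largest-|.| entry of each column positive
.fix_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Choose the number of embedding dimensions from the eigenvalue gaps
#'
#' Returns the largest `r` whose gap `lambda_r - lambda_{r+1}` exceeds
#' `threshold` times the mean consecutive gap, bounded to `[2, 50]`. The rule
#' automates the manual practice of stopping where pairwise eigenvector
#' scatter plots degrade into unstructured blobs; pass `override` to force a
#' specific `r`.
#'
#' @param eigenvalues Numeric vector of eigenvalues in descending order
#'   (length `>= 3`).
#' @param threshold Gap-dominance multiplier.
#' @param override If non-`NULL`, returned unchanged.
#' @return Integer `r`.
#' @export
select_dimensions <- function(eigenvalues, threshold = 2, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(length(eigenvalues) >= 3)
  gaps <- -diff(eigenvalues)
  big <- which(gaps > mean(gaps) * threshold)
  r <- if (length(big)) max(big) else 2L
  as.integer(min(max(r, 2L), 50L))
}

#' Full-matrix embedding pipeline
#'
#' Convenience wrapper: observed and expected Jaccard, depth model fitted on
#' a density sample, normalization, and spectral embedding.
#'
#' @param x A `cell_bin_matrix`.
#' @param r Number of embedding dimensions.
#' @param sample_size Cells used to fit the depth model.
#' @param normalize If `FALSE`, skip depth correction and embed the raw
#'   Jaccard kernel (for diagnosing the depth confounder).
#' @param seed Integer seed.
#' @return A `spectral_embedding` with the fitted `depth_model` attached as
#'   `$depth_model` (`NULL` when `normalize = FALSE`).
#' @export
embed_matrix <- function(x, r, sample_size = 2000, normalize = TRUE, seed = 1) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  J <- jaccard_matrix(x)
  if (normalize) {
    model <- fit_depth_model(x, sample_size = sample_size, seed = seed)
    E <- expected_jaccard(x$p)
    N <- normalize_jaccard(J, E, model)
  } else {
    model <- NULL
    N <- J
  }
  emb <- spectral_embed(N, r)
  emb$depth_model <- model
  emb
}
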