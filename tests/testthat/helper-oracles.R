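# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive (double loops, dense algebra)
# so it cannot share a code path with the implementation it checks.

# simulate -> binarized matrix in one step
sim_bin_matrix <- function(n_pops, cells_per_pop, m_bins = 5000,
                           coverage_range = c(1000, 5000),
                           rare_pop_fraction = 0, seed = 1,
                           profile_seed = seed) {
  prof <- make_profiles(n_pops, m_bins, seed = profile_seed)
  ds <- simulate_cells(prof, cells_per_pop, coverage_range = coverage_range,
                       rare_pop_fraction = rare_pop_fraction, seed = seed)
  list(x = binarize(as_bin_counts(ds), top_fraction = 0), truth = ds$labels,
       dataset = ds)
}

# naive pairwise Jaccard by double loop over dense rows
jaccard_brute <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- sum(X[i, ] & X[j, ])
    J[i, j] <- inter / sum(X[i, ] | X[j, ])
  }
  J
}

# naive k nearest neighbours, ties by lower index
knn_brute <- function(U, k) {
  n <- nrow(U)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(U) - U[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# naive connectivity index
connectivity_brute <- function(U, labels, K) {
  n <- nrow(U)
  total <- 0
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(U) - U[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(K)]
    total <- total + sum((labels[nb] != labels[i]) / seq_len(K))
  }
  total
}

# pair-counting ARI from first principles (loop over all pairs)
ari_brute <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  np <- s11 + s10 + s01 + s00
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# orthogonal Procrustes residual with a global scale, relative to ||A||_F
procrustes_residual <- function(A, B) {
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  scale <- sum(s$d) / sum(B^2)
  norm(A - scale * B %*% R, "F") / norm(A, "F")
}

# principal angles (radians) between the column spaces of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}

# write a small fragment data.frame to a temp TSV
write_frag_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}
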