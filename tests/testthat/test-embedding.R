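test_that("jaccard_matrix matches hand values and the brute-force oracle", {
  X <- Matrix::Matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0)), sparse = TRUE)
  J <- jaccard_matrix(X)
  expect_equal(diag(J), rep(1, 3), ignore_attr = TRUE)
  expect_equal(J[1, 2], 1 / 3)
  expect_equal(J[1, 3], 1) # identical rows
  expect_equal(J, t(J))
  # disjoint supports
  Y <- Matrix::Matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), sparse = TRUE)
  expect_equal(jaccard_matrix(Y)[1, 2], 0)
  # brute-force oracle on random binary rows
  set.seed(11)
  Z <- Matrix::Matrix(matrix(rbinom(30 * 40, 1, 0.3), 30, 40), sparse = TRUE)
  Z <- Z[Matrix::rowSums(Z) > 0, ]
  expect_equal(as.matrix(jaccard_matrix(Z)), jaccard_brute(Z),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero-coverage cell rejected by name
  bad <- Matrix::Matrix(rbind(a = c(1, 0), b = c(0, 0)), sparse = TRUE)
  expect_error(jaccard_matrix(bad), "zero-coverage")
})

test_that("expected_jaccard matches closed form and a Monte-Carlo oracle", {
  expect_equal(expected_jaccard(c(1, 1))[1, 2], 1)
  expect_equal(expected_jaccard(c(0.5, 0.5))[1, 2], 1 / 3)
  expect_error(expected_jaccard(c(0, 0.5)), "P_i = 0")
  # E strictly increasing in P_i for fixed P_j
  p_grid <- seq(0.05, 0.95, by = 0.05)
  e_col <- expected_jaccard(p_grid, 0.3)[, 1]
  expect_true(all(diff(e_col) > 0))
  # Monte-Carlo oracle: random binary vectors, m = 10000
  set.seed(42)
  m <- 10000; B <- 300
  pi <- 0.1; pj <- 0.2
  draws <- replicate(B, {
    xi <- rbinom(m, 1, pi); xj <- rbinom(m, 1, pj)
    sum(xi & xj) / sum(xi | xj)
  })
  e_theory <- pi * pj / (pi + pj - pi * pj)
  se <- sd(draws) / sqrt(B)
  expect_lt(abs(mean(draws) - e_theory), 3 * se + 1e-4)
})

test_that("sample_by_density is uniform for equal coverage and boosts rare modes", {
  expect_equal(sample_by_density(rep(100, 20), 20), 1:20)
  expect_error(sample_by_density(rep(100, 5), 6), "size exceeds")
  expect_error(sample_by_density(c(0, 10), 1), "positive")
  # bimodal coverage: rare mode sampled above its 10% frequency
  set.seed(3)
  cov <- c(round(10^rnorm(900, 3, 0.05)), round(10^rnorm(100, 4, 0.05)))
  hits <- vapply(1:200, function(s) {
    idx <- sample_by_density(cov, 100, seed = s)
    mean(idx > 900)
  }, numeric(1))
  expect_gt(mean(hits), 0.15)
  # determinism
  expect_identical(sample_by_density(cov, 50, seed = 9),
                   sample_by_density(cov, 50, seed = 9))
})

test_that("fit_depth_model recovers known polynomial coefficients", {
  # build a matrix whose J and E are controlled through simulation, then
  # verify OLS recovery by fitting on synthetic (J, E) pairs directly
  fx <- sim_bin_matrix(1, 120, m_bins = 3000, coverage_range = c(500, 3000),
                       seed = 5)
  model <- fit_depth_model(fx$x, sample_size = 120, seed = 1)
  expect_length(model$beta, 3)
  expect_true(is.finite(model$cap_value))
  # clamping: sample_size above n fits on all cells
  expect_equal(length(model$sampled), 120)
  # noiseless quadratic recovery through the same OLS design
  set.seed(31)
  e <- runif(500, 0.05, 0.5)
  j <- 0.1 + 0.5 * e + 0.2 * e^2
  expect_equal(unname(coef(lm(j ~ e + I(e^2)))), c(0.1, 0.5, 0.2),
               tolerance = 1e-6)
  # degenerate (constant E) falls back to the intercept-only model
  Xc <- Matrix::sparseMatrix(i = rep(1:5, each = 2),
                             j = c(rbind(1L, 2:6)), x = 1, dims = c(5, 10))
  const <- structure(list(X = Xc, coverage = Matrix::rowSums(Xc),
                          p = Matrix::rowSums(Xc) / 10),
                     class = "cell_bin_matrix")
  expect_warning(md <- fit_depth_model(const, sample_size = 5, seed = 1),
                 "degenerate")
  expect_equal(md$beta[2:3], c(0, 0))
})

test_that("normalize_jaccard divides by the fit, caps outliers, sets diagonal", {
  model <- structure(list(beta = c(0, 1, 0), cap_value = 10),
                     class = "depth_model")
  p <- seq(0.1, 0.6, length.out = 20)
  E <- expected_jaccard(p)
  J <- E # identity model: N should be 1 off-diagonal
  N <- normalize_jaccard(J, E, model)
  off <- row(N) != col(N)
  expect_equal(unname(N[off]), rep(1, sum(off)))
  expect_equal(unname(diag(N)), rep(1, 20))
  # capping contract: max equals the 0.99 quantile of pre-cap values
  set.seed(8)
  J2 <- E * exp(rnorm(length(E), 0, 0.3))
  J2 <- (J2 + t(J2)) / 2
  raw <- J2 / E
  cap <- quantile(raw[upper.tri(raw)], 0.99) # quantile over unique pairs
  N2 <- normalize_jaccard(J2, E, model)
  expect_equal(max(N2[off]), unname(cap))
  # non-positive prediction is an error
  bad <- structure(list(beta = c(-1, 0, 0), cap_value = 1), class = "depth_model")
  expect_error(normalize_jaccard(J, E, bad), "non-positive")
})

test_that("spectral_embed matches a dense eigensolver and separates blocks", {
  set.seed(21)
  # random symmetric positive kernel
  B <- matrix(runif(50 * 5), 50, 5)
  N <- B %*% t(B) + diag(50) * 0.1
  emb <- spectral_embed(N, r = 49)
  D <- rowSums(N)
  A <- diag(1 / sqrt(D)) %*% N %*% diag(1 / sqrt(D))
  # reconstruction over full rank within 1e-8
  eigA <- eigen(A, symmetric = TRUE)
  expect_lt(norm(eigA$vectors %*% diag(eigA$values) %*% t(eigA$vectors) - A,
                 "F"), 1e-8)
  # returned eigenpairs agree with the oracle up to sign
  expect_equal(emb$eigenvalues, eigA$values[1:49], tolerance = 1e-10)
  expect_equal(abs(emb$U), abs(eigA$vectors[, 1:49]), tolerance = 1e-8)
  # eigenvalues weakly decreasing, columns orthonormal
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_equal(crossprod(emb$U), diag(49), tolerance = 1e-8, ignore_attr = TRUE)
  # two disconnected equal blocks: top-2 eigenvectors separate them
  Nb <- matrix(0, 20, 20)
  Nb[1:10, 1:10] <- 0.5; Nb[11:20, 11:20] <- 0.5
  emb2 <- spectral_embed(Nb, r = 2)
  # rows are block-constant, and the two block representatives differ
  expect_equal(emb2$U[1:10, ], emb2$U[rep(1, 10), ], tolerance = 1e-10)
  expect_equal(emb2$U[11:20, ], emb2$U[rep(11, 10), ], tolerance = 1e-10)
  expect_gt(sqrt(sum((emb2$U[1, ] - emb2$U[11, ])^2)), 0.1)
  # zero row sum names the cell
  Nz <- diag(c(1, 1, 0))
  expect_error(spectral_embed(Nz, 2), "zero row sum")
})

test_that("select_dimensions applies the dominant-gap rule with bounds", {
  expect_equal(select_dimensions(c(1.0, 0.9, 0.1, 0.09, 0.08)), 2L)
  expect_equal(select_dimensions(0.5^(0:9)), 2L) # geometric decay
  expect_equal(select_dimensions(c(1, 0.9, 0.1), override = 15), 15L)
  # two dominant gaps: the larger r wins
  ev <- c(1, 0.95, 0.5, 0.45, 0.44, 0.43)
  expect_equal(select_dimensions(ev), 2L)
  expect_gte(select_dimensions(rep(1, 5) - (0:4) * 1e-3), 2L)
})

test_that("depth correction removes the coverage confounder on one population", {
  # one population = one bulk-like accessibility profile (no marker contrast)
  prof <- make_profiles(1, 20000, marker_fraction = 0, seed = 1)
  ds <- simulate_cells(prof, 400, coverage_range = c(1000, 10000), seed = 13)
  x <- binarize(as_bin_counts(ds), 0)
  emb_raw <- embed_matrix(x, r = 5, normalize = FALSE)
  emb_norm <- embed_matrix(x, r = 5, seed = 1)
  lc <- log10(x$coverage)
  expect_gt(abs(cor(emb_raw$U[, 1], lc)), 0.8)
  expect_lt(abs(cor(emb_norm$U[, 1], lc)), 0.2)
})

test_that("depth model from a density subsample matches the full fit", {
  fx <- sim_bin_matrix(1, 600, m_bins = 5000, coverage_range = c(1000, 10000),
                       seed = 17)
  J <- jaccard_matrix(fx$x)
  E <- expected_jaccard(fx$x$p)
  m_sub <- fit_depth_model(fx$x, sample_size = 200, seed = 2)
  m_full <- fit_depth_model(fx$x, sample_size = 600, seed = 2)
  N_sub <- normalize_jaccard(J, E, m_sub)
  N_full <- normalize_jaccard(J, E, m_full)
  off <- upper.tri(N_sub)
  expect_gt(cor(N_sub[off], N_full[off]), 0.99)
})
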