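# shared fixture: reference/query split of a 3-population simulation
make_transfer_fixture <- function(seed = 51) {
  fx <- sim_bin_matrix(3, 120, m_bins = 5000, coverage_range = c(1500, 4000),
                       seed = seed)
  n <- nrow(fx$x$X)
  set.seed(seed)
  query_idx <- sort(sample.int(n, 72)) # 20% hold-out
  ref_idx <- setdiff(seq_len(n), query_idx)
  subset_x <- function(idx) {
    structure(list(X = fx$x$X[idx, , drop = FALSE],
                   coverage = fx$x$coverage[idx], p = fx$x$p[idx],
                   bin_coords = fx$x$bin_coords, bin_size = fx$x$bin_size,
                   kept_bins = fx$x$kept_bins),
              class = "cell_bin_matrix")
  }
  list(ref = subset_x(ref_idx), query = subset_x(query_idx),
       ref_labels = fx$truth[ref_idx], query_labels = fx$truth[query_idx])
}

test_that("project_query is consistent for duplicated cells and empty input", {
  fix <- make_transfer_fixture()
  model <- fit_landmarks(fix$ref, k = 150, r = 6, seed = 2)
  pr <- project_query(model, fix$query)
  expect_equal(dim(pr$U_query), c(72, 6))
  expect_equal(nrow(pr$joint), 150 + 72)
  # two copies of one cell project identically
  dup <- fix$query$X[c(1, 1), , drop = FALSE]
  U2 <- nystrom_extend(model, dup)
  expect_equal(U2[1, ], U2[2, ])
  # a query equal to a landmark lands on that landmark's reconstruction
  copy <- model$X_land[5, , drop = FALSE]
  expect_lt(sqrt(sum((nystrom_extend(model, copy) - model$U_kk[5, ])^2)) /
              sqrt(sum(model$U_kk[5, ]^2)), 1e-6)
  # empty query
  expect_equal(nrow(nystrom_extend(model, fix$query$X[0, , drop = FALSE])), 0)
})

test_that("find_anchors matches a brute-force mutual-nearest-neighbor search", {
  set.seed(53)
  U_ref <- matrix(rnorm(60 * 4), 60, 4)
  U_query <- matrix(rnorm(40 * 4), 40, 4)
  an <- find_anchors(U_ref, U_query, k_nearest = 5)
  # brute force double loop
  d <- as.matrix(dist(rbind(U_ref, U_query)))[1:60, 61:100]
  pairs <- list()
  for (i in 1:60) for (c_i in 1:40) {
    top_q <- order(d[i, ], seq_len(40))[1:5]
    top_r <- order(d[, c_i], seq_len(60))[1:5]
    if (c_i %in% top_q && i %in% top_r)
      pairs[[length(pairs) + 1]] <- c(i, c_i)
  }
  brute <- do.call(rbind, pairs)
  brute <- brute[order(brute[, 1], brute[, 2]), ]
  expect_equal(as.matrix(an$pairs), brute, ignore_attr = TRUE)
  # identical point sets anchor every cell to its copy
  an2 <- find_anchors(U_query, U_query, k_nearest = 5)
  self_pairs <- an2$pairs[an2$pairs$ref == an2$pairs$query, ]
  expect_equal(nrow(self_pairs), 40)
  expect_length(an2$unanchored_query, 0)
  # far-away outlier gets no anchor
  U_out <- rbind(U_query, matrix(100, 1, 4))
  an3 <- find_anchors(U_ref, U_out, k_nearest = 5)
  expect_true(41 %in% an3$unanchored_query)
})

test_that("score_anchors counts shared neighbors like the brute-force oracle", {
  set.seed(57)
  U_ref <- matrix(rnorm(30 * 3), 30, 3)
  U_query <- U_ref + matrix(rnorm(90, 0, 0.01), 30, 3)
  an <- find_anchors(U_ref, U_query, k_nearest = 3)
  scored <- score_anchors(an, U_ref, U_query, snn_k = 10)
  expect_true(all(scored$scores >= 0 & scored$scores <= 1))
  # raw shared-neighbor counts against a brute-force implementation
  joint <- rbind(U_ref, U_query)
  nnb <- knn_brute(joint, 10)
  raw_brute <- vapply(seq_len(nrow(an$pairs)), function(t) {
    a <- an$pairs$ref[t]; b <- 30 + an$pairs$query[t]
    length(intersect(nnb[a, ], nnb[b, ])) / 10
  }, numeric(1))
  lo <- quantile(raw_brute, 0.01); hi <- quantile(raw_brute, 0.90)
  expect_equal(scored$scores,
               pmin(pmax((raw_brute - lo) / max(hi - lo, 1e-300), 0), 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # near-duplicated datasets have a large mass at the clipped maximum
  expect_gt(mean(scored$scores == 1), 0.1)
})

test_that("transfer_weights follows the distance-score scheme and rows sum to 1", {
  set.seed(59)
  U_query <- matrix(rnorm(25 * 3), 25, 3)
  anchors <- structure(list(
    pairs = data.frame(ref = 1:10, query = sample(1:25, 10)),
    unanchored_query = integer(0), k_nearest = 5,
    scores = runif(10, 0.3, 1)), class = "anchor_set")
  w <- transfer_weights(U_query, anchors, s = 6, sd = 1)
  expect_equal(Matrix::rowSums(w$W), rep(1, 25), ignore_attr = TRUE,
               tolerance = 1e-12)
  # at most s anchors per row receive weight
  expect_true(all(Matrix::rowSums(w$W > 0) <= 6))
  # query sitting on an anchor: D = S for that anchor (zero distance)
  q_on <- anchors$pairs$query[1]
  U_query2 <- U_query
  U_query2[q_on, ] <- U_query2[anchors$pairs$query[1], ]
  d <- sqrt(colSums((t(U_query[anchors$pairs$query, ]) - U_query[q_on, ])^2))
  ord <- order(d, seq_len(10))[1:6]
  d_s <- d[ord[6]]
  D <- (1 - d[ord] / d_s) * anchors$scores[ord]
  expect_equal(D[1], anchors$scores[anchors$pairs$query == q_on][1])
  expect_equal(D[6], 0) # s-th anchor gets zero
  Dt <- 1 - exp(-D / 4) # (2/sd)^2 = 4 at sd = 1
  expect_equal(as.numeric(w$W[q_on, ord]), Dt / sum(Dt), tolerance = 1e-12)
})

test_that("predict_labels yields stochastic rows and permutation invariance", {
  set.seed(61)
  U_query <- matrix(rnorm(20 * 2), 20, 2)
  anchors <- structure(list(
    pairs = data.frame(ref = 1:8, query = rep(1:4, 2)),
    unanchored_query = c(19L, 20L), k_nearest = 5,
    scores = runif(8, 0.5, 1)), class = "anchor_set")
  w <- transfer_weights(U_query, anchors, s = 4)
  ref_labels <- rep(c("B", "T"), 4)
  pred <- predict_labels(w, ref_labels, threshold = 0.9)
  expect_equal(rowSums(pred$P), rep(1, 20), tolerance = 1e-12)
  expect_true(all(pred$P >= 0 & pred$P <= 1))
  expect_true(all(pred$flagged[c(19, 20)]))
  # permuting label names permutes predictions consistently
  swap <- c(B = "T", T = "B")
  pred2 <- predict_labels(w, unname(swap[ref_labels]), threshold = 0.9)
  expect_equal(unname(pred$P[, "B"]), unname(pred2$P[, "T"]))
  expect_equal(unname(swap[pred$best_label]), pred2$best_label)
  # all anchors of one query sharing a label give an indicator row
  one_lab <- rep("B", 8)
  pred3 <- predict_labels(w, one_lab)
  expect_equal(unname(pred3$P[, 1]), rep(1, 20))
})

test_that("transfer_coordinates is the anchor-weighted convex combination", {
  U_query <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  anchors <- structure(list(
    pairs = data.frame(ref = 1:3, query = 1:3),
    unanchored_query = integer(0), k_nearest = 5,
    scores = c(1, 1, 1)), class = "anchor_set")
  w <- transfer_weights(U_query, anchors, s = 3)
  coords <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  tc <- transfer_coordinates(w, coords)
  # rows lie in the convex hull of the anchors' coordinates
  expect_true(all(tc >= 0 & tc <= 10))
  expect_equal(tc, as.matrix(w$W %*% coords), ignore_attr = TRUE)
  # single anchor with weight 1 returns its coordinates
  a1 <- structure(list(pairs = data.frame(ref = 2, query = 1),
                       unanchored_query = integer(0), k_nearest = 5,
                       scores = 1), class = "anchor_set")
  w1 <- suppressWarnings(transfer_weights(U_query, a1, s = 1))
  expect_equal(as.numeric(transfer_coordinates(w1, coords)[1, ]), c(10, 0))
})

test_that("held-out label transfer is accurate and novel populations are flagged", {
  fix <- make_transfer_fixture(seed = 63)
  model <- fit_landmarks(fix$ref, k = nrow(fix$ref$X), r = 6, seed = 2)
  land_labels <- fix$ref_labels[model$landmark_indices]
  pr <- project_query(model, fix$query)
  an <- find_anchors(model$U_kk, pr$U_query, k_nearest = 5)
  an <- score_anchors(an, model$U_kk, pr$U_query, snn_k = 30)
  w <- transfer_weights(pr$U_query, an, s = 50)
  pred <- predict_labels(w, land_labels, threshold = 0.9)
  acc <- mean(pred$best_label == fix$query_labels)
  expect_gt(acc, 0.95)
  # drop population 3 from the reference; its query cells must be flagged
  keep <- fix$ref_labels != 3
  ref2 <- structure(list(X = fix$ref$X[keep, ], coverage = fix$ref$coverage[keep],
                         p = fix$ref$p[keep], bin_coords = fix$ref$bin_coords,
                         bin_size = fix$ref$bin_size, kept_bins = fix$ref$kept_bins),
                    class = "cell_bin_matrix")
  model2 <- fit_landmarks(ref2, k = nrow(ref2$X), r = 6, seed = 2)
  pr2 <- project_query(model2, fix$query)
  an2 <- find_anchors(model2$U_kk, pr2$U_query, k_nearest = 5)
  an2 <- score_anchors(an2, model2$U_kk, pr2$U_query, snn_k = 30)
  w2 <- transfer_weights(pr2$U_query, an2, s = 50)
  pred2 <- predict_labels(w2, fix$ref_labels[keep][model2$landmark_indices],
                          threshold = 0.9)
  novel <- fix$query_labels == 3
  expect_gt(mean(pred2$flagged[novel]), 0.8)
})
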