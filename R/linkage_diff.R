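#' Impute expression for accessibility cells from co-embedded RNA cells
#'
#' Given a joint embedding holding both modalities, each accessibility cell
#' receives the weighted average expression of its `k` nearest RNA cells.
#' Weights are Gaussian in distance with the bandwidth set per cell to the
#' distance of its `k`-th neighbor (uniform weights available via
#' `weighting = "uniform"`), producing "pseudo-cells" that pair chromatin
#' state with an expression estimate.
#'
#' @param atac_coords Embedding coordinates of the accessibility cells.
#' @param rna_coords Embedding coordinates of the RNA cells (same space).
#' @param expression RNA cells x genes matrix.
#' @param k Neighbors used per cell (clamped to the RNA cell count).
#' @param weighting `"gaussian"` (default) or `"uniform"`.
#' @return A list with `imputed` (accessibility cells x genes),
#'   `neighbor_ids` (n x k RNA indices), `weights` (n x k, rows sum to 1).
#' @export
impute_expression <- function(atac_coords, rna_coords, expression, k = 15,
                              weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  atac_coords <- as.matrix(atac_coords); rna_coords <- as.matrix(rna_coords)
  stopifnot(ncol(atac_coords) == ncol(rna_coords),
            nrow(rna_coords) == nrow(expression))
  k_eff <- min(k, nrow(rna_coords))
  nn <- .knn_index(rna_coords, atac_coords, k = k_eff, exclude_self = FALSE)
  W <- matrix(0, nrow(atac_coords), k_eff)
  for (i in seq_len(nrow(atac_coords))) {
    d <- nn$dist[i, ]
    if (weighting == "uniform" || d[k_eff] == 0) {
      w <- rep(1, k_eff)
    } else {
      w <- exp(-(d / d[k_eff])^2)
    }
    W[i, ] <- w / sum(w)
  }
  expression <- as.matrix(expression)
  imputed <- matrix(0, nrow(atac_coords), ncol(expression),
                    dimnames = list(rownames(atac_coords), colnames(expression)))
  for (i in seq_len(nrow(atac_coords)))
    imputed[i, ] <- W[i, ] %*% expression[nn$index[i, ], , drop = FALSE]
  list(imputed = imputed, neighbor_ids = nn$index, weights = W)
}

#' Enhancer-gene association by logistic regression
#'
#' For one gene, regresses the binary accessibility state of each candidate
#' peak (restricted to `window` bp around the gene when distances are
#' supplied) on the imputed expression with a logit link, reporting the
#' slope `beta1`, its Wald p-value, and significance at the genome-wide
#' `alpha` cutoff. Peaks that are constant across cells are skipped
#' (`degenerate response`); fits showing (quasi-)separation are flagged.
#'
#' @param expression Imputed expression of the gene across pseudo-cells.
#' @param peaks Binary matrix (pseudo-cells x peaks) of peak states.
#' @param peak_distances Optional signed distance of each peak to the gene
#'   TSS in bp; peaks beyond `window` are dropped.
#' @param window Flanking window around the TSS in bp.
#' @param alpha Significance cutoff on the Wald p-value.
#' @return data.frame with one row per tested peak: `peak`, `distance`,
#'   `beta1`, `p_value`, `significant`, `flag` (`"ok"`, `"separation"`), and
#'   attribute `skipped` listing degenerate peaks.
#' @export
link_gene <- function(expression, peaks, peak_distances = NULL,
                      window = 1e6, alpha = 5e-8) {
  peaks <- as.matrix(peaks)
  stopifnot(length(expression) == nrow(peaks))
  ids <- colnames(peaks)
  if (is.null(ids)) ids <- sprintf("peak%d", seq_len(ncol(peaks)))
  if (!is.null(peak_distances)) {
    stopifnot(length(peak_distances) == ncol(peaks))
    keep <- abs(peak_distances) <= window
    peaks <- peaks[, keep, drop = FALSE]
    ids <- ids[keep]
    peak_distances <- peak_distances[keep]
  }
  res <- vector("list", ncol(peaks))
  skipped <- character(0)
  for (j in seq_len(ncol(peaks))) {
    y <- peaks[, j]
    if (all(y == y[1])) {
      skipped <- c(skipped, ids[j])
      next
    }
    fit <- suppressWarnings(glm(y ~ expression, family = binomial(link = "logit")))
    sm <- summary(fit)$coefficients
    beta1 <- sm["expression", "Estimate"]
    p <- sm["expression", "Pr(>|z|)"]
    sep <- !fit$converged || abs(beta1) > 20
    res[[j]] <- data.frame(
      peak = ids[j],
      distance = if (is.null(peak_distances)) NA_real_ else peak_distances[j],
      beta1 = beta1, p_value = p,
      significant = is.finite(p) && p < alpha,
      flag = if (sep) "separation" else "ok")
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(peak = character(), distance = numeric(),
                      beta1 = numeric(), p_value = numeric(),
                      significant = logical(), flag = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Distance-matched negative-control peaks
#'
#' For each positive gene-peak pair at signed TSS distance `d`, selects the
#' candidate peak on the *opposite* side of the TSS whose absolute distance
#' is closest to `|d|` (ties toward the smaller absolute distance). Pairs
#' without any opposite-side candidate are skipped and counted.
#'
#' @param positive_pairs data.frame with columns `gene`, `peak`, `distance`
#'   (signed bp from the TSS).
#' @param candidate_peaks data.frame with columns `gene`, `peak`, `distance`
#'   (signed) listing candidates per gene.
#' @return data.frame of matched pairs (`gene`, `peak`,
#'   `distance`, `matched_peak`, `matched_distance`) with attribute
#'   `n_skipped`.
#' @export
negative_controls <- function(positive_pairs, candidate_peaks) {
  stopifnot(all(c("gene", "peak", "distance") %in% names(positive_pairs)),
            all(c("gene", "peak", "distance") %in% names(candidate_peaks)))
  out <- vector("list", nrow(positive_pairs))
  n_skipped <- 0L
  for (t in seq_len(nrow(positive_pairs))) {
    g <- positive_pairs$gene[t]
    d <- positive_pairs$distance[t]
    cand <- candidate_peaks[candidate_peaks$gene == g &
                              sign(candidate_peaks$distance) == -sign(d), ,
                            drop = FALSE]
    if (nrow(cand) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    gap <- abs(abs(d) - abs(cand$distance))
    best <- order(gap, abs(cand$distance))[1] # ties toward smaller |distance|
    out[[t]] <- data.frame(gene = g, peak = positive_pairs$peak[t],
                           distance = d,
                           matched_peak = cand$peak[best],
                           matched_distance = cand$distance[best])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), peak = character(),
                      distance = numeric(), matched_peak = character(),
                      matched_distance = numeric())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Matched background cells for a cluster
#'
#' For differential accessibility, the background of a cell group `C_i` is
#' its local neighborhood: the `|C_i|` cells outside the group closest to
#' the group centroid in the embedding. When the group holds more than half
#' of all cells, the complement is used instead (it is then the smaller
#' set).
#'
#' @param cells_i Integer indices of the group.
#' @param embedding Embedding matrix over all cells.
#' @return Integer indices of the background cells.
#' @export
select_background <- function(cells_i, embedding) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  cells_i <- sort(unique(as.integer(cells_i)))
  if (length(cells_i) == n) stop("group covers every cell; no background exists")
  outside <- setdiff(seq_len(n), cells_i)
  if (length(cells_i) > n / 2) return(outside)
  centroid <- colMeans(embedding[cells_i, , drop = FALSE])
  d2 <- colSums((t(embedding[outside, , drop = FALSE]) - centroid)^2)
  outside[order(d2, outside)[seq_along(cells_i)]]
}

#' Aggregate peak counts over a cell group
#'
#' @param cells Integer indices of the group (non-empty).
#' @param peak_counts Cells x peaks count matrix.
#' @return Numeric vector of per-peak summed counts.
#' @export
aggregate_counts <- function(cells, peak_counts) {
  if (length(cells) == 0) stop("empty cell group")
  v <- Matrix::colSums(peak_counts[cells, , drop = FALSE])
  as.numeric(v)
}

# two-sided conditional NB exact test p-value for one peak.
# Conditions on s = y1 + y2 after library equalization; under the null both
# counts are NB with equal mean and dispersion phi, and the p-value sums the
# conditional probabilities not exceeding that of the observed split.
.nb_exact_p <- function(y1, y2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  size <- if (phi > 0) 1 / phi else Inf
  mu <- s / 2
  if (is.finite(size)) {
    lp <- dnbinom(k, size = size, mu = mu, log = TRUE) +
      dnbinom(s - k, size = size, mu = mu, log = TRUE)
  } else {
    lp <- stats::dpois(k, mu, log = TRUE) + stats::dpois(s - k, mu, log = TRUE)
  }
  lp <- lp - max(lp)
  p_all <- exp(lp)
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[y1 + 1]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-10)]))
}

#' Differential accessibility by a fixed-dispersion NB exact test
#'
#' Compares two aggregated count vectors peak by peak with a conditional
#' negative-binomial exact test at fixed dispersion `bcv^2` (the squared
#' biological coefficient of variation). Library sizes are equalized by
#' rescaling both vectors to their geometric-mean total before testing;
#' conditioning on the per-peak sum then makes the null symmetric, and the
#' two-sided p-value accumulates all splits at most as probable as the
#' observed one. In the `bcv -> 0` limit the test reduces to the binomial
#' exact test. P-values are Benjamini-Hochberg adjusted; peaks with
#' `fdr < fdr_cutoff` are significant.
#'
#' @param v_ci,v_cj Per-peak aggregated counts of the group and its matched
#'   background (equal length, positive totals).
#' @param bcv Biological coefficient of variation; dispersion is `bcv^2`.
#' @param fdr_cutoff FDR threshold for the `significant` flag.
#' @return data.frame per peak: `log_fc` (log2 of normalized means),
#'   `p_value`, `fdr`, `significant`.
#' @export
differential_test <- function(v_ci, v_cj, bcv = 0.1, fdr_cutoff = 0.05) {
  stopifnot(length(v_ci) == length(v_cj))
  n1 <- sum(v_ci); n2 <- sum(v_cj)
  if (n1 <= 0 || n2 <= 0) stop("both groups need positive total counts")
  target <- sqrt(n1 * n2)
  y1 <- round(v_ci * target / n1)
  y2 <- round(v_cj * target / n2)
  phi <- bcv^2
  p <- vapply(seq_along(y1), function(j) .nb_exact_p(y1[j], y2[j], phi),
              numeric(1))
  zero <- (y1 + y2) == 0
  p[zero] <- 1
  log_fc <- log2((y1 + 0.5) / (y2 + 0.5))
  log_fc[zero] <- 0
  fdr <- p.adjust(p, method = "BH")
  data.frame(log_fc = log_fc, p_value = p, fdr = fdr,
             significant = fdr < fdr_cutoff)
}
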