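#' Build population accessibility profiles
#'
#' Generates `n_pops` per-bin accessibility probability profiles sharing a
#' common baseline, each population elevated over a disjoint set of marker
#' bins. The profiles act as the bulk-like ground truth from which single
#' cells are downsampled by [simulate_cells()].
#'
#' @param n_pops Number of populations.
#' @param m_bins Number of genomic bins per profile.
#' @param marker_fraction Fraction of bins reserved as markers for each
#'   population (disjoint across populations).
#' @param base_rate Baseline accessibility probability of a non-marker bin.
#' @param marker_boost Multiplicative boost applied to a population's own
#'   marker bins.
#' @param seed Integer seed; the output is deterministic given the seed.
#'
#' @return A list with `probs` (an `n_pops x m_bins` matrix of per-bin
#'   probabilities in `[0,1]`), `marker_bins` (list of integer vectors, one
#'   per population, pairwise disjoint), and the generating parameters.
#' @export
make_profiles <- function(n_pops, m_bins, marker_fraction = 0.02,
                          base_rate = 0.02, marker_boost = 3, seed = 1) {
  stopifnot(n_pops >= 1, m_bins >= 1, marker_fraction >= 0, marker_fraction < 1)
  n_marker <- floor(marker_fraction * m_bins)
  if (marker_fraction > 0 && n_marker < 1)
    stop("marker_fraction * m_bins < 1: no marker bins per population")
  if (n_pops * n_marker > m_bins)
    stop("not enough bins for disjoint marker sets")
  set.seed(seed)
  # shared baseline with lognormal bin-to-bin variation, as in bulk coverage
  baseline <- base_rate * rlnorm(m_bins, meanlog = 0, sdlog = 0.5)
  baseline <- pmin(baseline, 1)
  marker_pool <- if (n_marker > 0) sample.int(m_bins, n_pops * n_marker) else integer(0)
  marker_bins <- lapply(seq_len(n_pops), function(p) {
    if (n_marker == 0) return(integer(0))
    sort(marker_pool[seq((p - 1) * n_marker + 1, p * n_marker)])
  })
  probs <- matrix(rep(baseline, each = n_pops), nrow = n_pops)
  for (p in seq_len(n_pops)) {
    mk <- marker_bins[[p]]
    if (length(mk) == 0) next
    # markers are elevated only in their own population; other populations
    # keep the shared baseline there, so between-population profile
    # correlation stays in the realistic bulk range (~0.75 at defaults)
    probs[p, mk] <- pmin(probs[p, mk] * marker_boost, 1)
  }
  structure(list(probs = probs, marker_bins = marker_bins,
                 n_pops = n_pops, m_bins = m_bins,
                 base_rate = base_rate, marker_boost = marker_boost,
                 seed = seed),
            class = "population_profiles")
}

#' Simulate single cells by downsampling population profiles
#'
#' Each cell draws a target coverage log-uniformly from `coverage_range`
#' (emulating the 1,000-10,000 reads-per-cell regime of shallow single-cell
#' chromatin data) and places that many reads multinomially across bins with
#' probabilities proportional to its population profile. Optionally a rare
#' population is spiked in: the *last* profile is treated as the rare
#' population and receives `round(rare_pop_fraction * n_total)` cells while
#' the remaining profiles each receive `cells_per_pop` cells.
#'
#' @param profiles A `population_profiles` object from [make_profiles()].
#' @param cells_per_pop Cells per (non-rare) population; scalar or vector.
#' @param coverage_range Length-2 numeric, inclusive range of reads per cell;
#'   coverages are drawn log-uniformly.
#' @param rare_pop_fraction If `> 0`, fraction of the total cell count taken
#'   by the rare (last) population.
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_dataset` with `counts` (sparse
#'   cells-by-bins dgCMatrix), `labels` (integer population per cell),
#'   `coverage` (target reads per cell), and `profiles`.
#' @export
simulate_cells <- function(profiles, cells_per_pop,
                           coverage_range = c(1000, 10000),
                           rare_pop_fraction = 0, seed = 1) {
  stopifnot(inherits(profiles, "population_profiles"),
            all(coverage_range > 0), length(coverage_range) == 2)
  n_pops <- profiles$n_pops
  if (rare_pop_fraction > 0 && n_pops < 2)
    stop("rare spike-in requires at least 2 profiles")
  set.seed(seed)
  if (rare_pop_fraction > 0) {
    main_pops <- seq_len(n_pops - 1L)
    n_main <- rep_len(cells_per_pop, n_pops - 1L)
    n_rare <- max(1L, round(sum(n_main) * rare_pop_fraction / (1 - rare_pop_fraction)))
    n_cells_pop <- c(n_main, n_rare)
  } else {
    n_cells_pop <- rep_len(cells_per_pop, n_pops)
  }
  labels <- rep(seq_len(n_pops), times = n_cells_pop)
  n <- length(labels)
  coverage <- round(10^runif(n, log10(coverage_range[1]), log10(coverage_range[2])))
  m <- profiles$m_bins
  # multinomial read placement at fixed per-cell depth
  trip_i <- vector("list", n); trip_j <- vector("list", n); trip_x <- vector("list", n)
  for (p in seq_len(n_pops)) {
    idx <- which(labels == p)
    if (!length(idx)) next
    pr <- profiles$probs[p, ]
    pr <- pr / sum(pr)
    for (ii in seq_along(idx)) {
      cell <- idx[ii]
      cnt <- rmultinom(1, size = coverage[cell], prob = pr)[, 1]
      nz <- which(cnt > 0)
      trip_i[[cell]] <- rep.int(cell, length(nz))
      trip_j[[cell]] <- nz
      trip_x[[cell]] <- cnt[nz]
    }
  }
  counts <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                 x = unlist(trip_x), dims = c(n, m))
  rownames(counts) <- sprintf("cell%05d", seq_len(n))
  structure(list(counts = counts, labels = labels, coverage = coverage,
                 profiles = profiles, seed = seed),
            class = "synthetic_dataset")
}

#' View a synthetic dataset as cell-by-bin counts
#'
#' Lays the simulated bins on a single synthetic chromosome tiled at
#' `bin_size` so the dataset can enter the standard matrix pipeline
#' ([binarize()], [filter_bins()], ...).
#'
#' @param dataset A `synthetic_dataset`.
#' @param bin_size Bin width in bp used for the synthetic coordinates.
#' @param chrom Chromosome name.
#' @return A `cell_bin_counts`.
#' @export
as_bin_counts <- function(dataset, bin_size = 5000, chrom = "chr1") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  m <- ncol(dataset$counts)
  bin_coords <- data.frame(chrom = chrom,
                           start = (seq_len(m) - 1) * bin_size,
                           end = seq_len(m) * bin_size)
  structure(list(counts = dataset$counts,
                 cell_barcodes = rownames(dataset$counts),
                 bin_coords = bin_coords, bin_size = bin_size),
            class = "cell_bin_counts")
}

#' Downsample a synthetic dataset by binomial thinning
#'
#' Each count is replaced by a Binomial(count, `keep_fraction`) draw,
#' emulating a re-sequencing of the same library at reduced depth. Labels are
#' preserved.
#'
#' @param dataset A `synthetic_dataset`.
#' @param keep_fraction Probability of keeping each read, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `synthetic_dataset` with thinned counts.
#' @export
perturb_depth <- function(dataset, keep_fraction = 0.9, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            keep_fraction > 0, keep_fraction <= 1)
  if (keep_fraction == 1) return(dataset)
  set.seed(seed)
  cnt <- as(dataset$counts, "TsparseMatrix")
  x_new <- rbinom(length(cnt@x), size = cnt@x, prob = keep_fraction)
  keep <- x_new > 0
  thinned <- Matrix::sparseMatrix(i = cnt@i[keep] + 1L, j = cnt@j[keep] + 1L,
                                  x = x_new[keep], dims = dim(cnt),
                                  dimnames = dimnames(cnt))
  out <- dataset
  out$counts <- thinned
  out$coverage <- Matrix::rowSums(thinned)
  out
}

#' Render a synthetic dataset as a fragment file
#'
#' Emits one fragment per read count, placed uniformly within its bin so that
#' no fragment crosses a bin boundary; round-tripping through
#' [build_bin_matrix()] therefore reproduces the counts exactly. Fragments are
#' laid out on a single synthetic chromosome tiled at `bin_size`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param bin_size Bin width in bp.
#' @param frag_len Fragment length in bp; must be `< bin_size`.
#' @param chrom Chromosome name used for all bins.
#' @param path Optional path; when given, the fragments are written as a
#'   4-column TSV (chrom, start, end, barcode).
#' @param seed Integer seed for the uniform placement.
#'
#' @return A list with `fragments` (data.table chrom/start/end/barcode),
#'   `chrom_sizes` (named vector), and `bins` (data.table chrom/start/end).
#' @export
render_fragments <- function(dataset, bin_size = 5000, frag_len = 200,
                             chrom = "chr1", path = NULL, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (frag_len >= bin_size) stop("frag_len must be smaller than bin_size")
  set.seed(seed)
  cnt <- as(dataset$counts, "TsparseMatrix")
  m <- ncol(cnt)
  reps <- cnt@x
  cell_idx <- rep.int(cnt@i + 1L, reps)
  bin_idx <- rep.int(cnt@j, reps) # 0-based bin index
  offset <- floor(runif(length(cell_idx), 0, bin_size - frag_len + 1))
  start <- bin_idx * bin_size + offset
  frags <- data.table::data.table(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + frag_len),
    barcode = rownames(cnt)[cell_idx]
  )
  data.table::setorder(frags, barcode, start)
  chrom_sizes <- setNames(m * bin_size, chrom)
  bins <- data.table::data.table(chrom = chrom,
                                 start = (seq_len(m) - 1L) * bin_size,
                                 end = seq_len(m) * bin_size)
  if (!is.null(path))
    data.table::fwrite(frags, path, sep = "\t", col.names = FALSE)
  list(fragments = frags, chrom_sizes = chrom_sizes, bins = bins)
}

#' Simulate paired expression with ground-truth enhancer links
#'
#' Generates pseudo-cell level data for benchmarking enhancer-gene linkage:
#' per-cell expression is log-normal around a population program, and each
#' *linked* gene has one true enhancer peak whose binary accessibility follows
#' a logistic model in the gene's (scaled) expression with slope
#' `effect_size`. Unlinked decoy peaks are Bernoulli with a constant rate.
#'
#' @param profiles A `population_profiles` object (defines the populations).
#' @param n_cells Number of pseudo-cells.
#' @param linked_genes Number of genes carrying a true enhancer link.
#' @param decoy_peaks Number of additional unlinked peaks per gene.
#' @param effect_size Logistic slope tying enhancer state to scaled
#'   expression; `0` yields a null dataset (empty truth table in effect).
#' @param seed Integer seed.
#'
#' @return A list with `expression` (cells x genes), `peaks` (binary cells x
#'   peaks matrix), `labels` (population per cell), and `truth` (data.frame
#'   gene/peak/linked flag per gene-peak pair).
#' @export
simulate_paired_rna <- function(profiles, n_cells, linked_genes = 10,
                                decoy_peaks = 4, effect_size = 2, seed = 1) {
  stopifnot(inherits(profiles, "population_profiles"), n_cells >= 2)
  set.seed(seed)
  n_pops <- profiles$n_pops
  labels <- sample(rep_len(seq_len(n_pops), n_cells))
  g <- linked_genes
  # population program: each gene high in one population
  pop_mean <- matrix(1, n_pops, g)
  owner <- rep_len(seq_len(n_pops), g)
  pop_mean[cbind(owner, seq_len(g))] <- 6
  logexpr <- log(pop_mean[labels, , drop = FALSE]) +
    matrix(rnorm(n_cells * g, sd = 0.4), n_cells, g)
  expression <- exp(logexpr)
  colnames(expression) <- sprintf("gene%03d", seq_len(g))
  n_peaks <- g * (1L + decoy_peaks)
  peaks <- matrix(0L, n_cells, n_peaks)
  truth <- vector("list", g)
  peak_id <- 0L
  for (j in seq_len(g)) {
    z <- scale(expression[, j])[, 1]
    peak_id <- peak_id + 1L
    peaks[, peak_id] <- rbinom(n_cells, 1L, stats::plogis(-0.5 + effect_size * z))
    rows <- data.frame(gene = colnames(expression)[j],
                       peak = sprintf("peak%04d", peak_id),
                       linked = effect_size != 0)
    for (d in seq_len(decoy_peaks)) {
      peak_id <- peak_id + 1L
      peaks[, peak_id] <- rbinom(n_cells, 1L, 0.35)
      rows <- rbind(rows, data.frame(gene = colnames(expression)[j],
                                     peak = sprintf("peak%04d", peak_id),
                                     linked = FALSE))
    }
    truth[[j]] <- rows
  }
  colnames(peaks) <- sprintf("peak%04d", seq_len(n_peaks))
  list(expression = expression, peaks = peaks, labels = labels,
       truth = do.call(rbind, truth))
}
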