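#' Read a fragment file with insert-size filtering
#'
#' Reads a 4-column TSV of mapped fragments (chrom, start, end, barcode;
#' optionally gzip-compressed), drops fragments on chromosomes absent from
#' `chrom_sizes` (with a logged count), rejects records with `start >= end`,
#' and keeps only fragments whose insert size lies within
#' `[min_insert, max_insert]` (inclusive). Coordinates are 0-based half-open
#' (BED convention).
#'
#' @param path Path to the fragment TSV (chrom, start, end, barcode).
#' @param chrom_sizes Named numeric vector of chromosome lengths, or a
#'   2-column data.frame (chrom, length).
#' @param min_insert,max_insert Inclusive insert-size bounds in bp.
#'
#' @return A `fragment_set`: list with `fragments` (data.table sorted by
#'   barcode), `chrom_sizes`, and counts of dropped records
#'   (`n_bad_coord`, `n_unknown_chrom`, `n_bad_insert`).
#' @export
read_fragments <- function(path, chrom_sizes, min_insert = 50, max_insert = 1000) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  frags <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1, integer = 2:3, character = 4)),
    error = function(e) stop("failed to parse fragment file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(frags) < 4)
    stop("fragment file must have at least 4 columns (chrom, start, end, barcode)")
  frags <- frags[, 1:4]
  data.table::setnames(frags, c("chrom", "start", "end", "barcode"))
  as_fragment_set(frags, chrom_sizes, min_insert, max_insert)
}

#' Construct a fragment set from an in-memory table
#'
#' Applies the same coordinate checks and insert-size filter as
#' [read_fragments()] to a data.frame already in memory.
#'
#' @inheritParams read_fragments
#' @param frags data.frame/data.table with columns chrom, start, end, barcode.
#' @return A `fragment_set` (see [read_fragments()]).
#' @export
as_fragment_set <- function(frags, chrom_sizes, min_insert = 50, max_insert = 1000) {
  stopifnot(min_insert <= max_insert)
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  frags <- data.table::as.data.table(frags)[, 1:4]
  data.table::setnames(frags, c("chrom", "start", "end", "barcode"))
  if (any(frags$barcode == "")) stop("empty barcode in fragment input")
  bad_coord <- frags$start >= frags$end | frags$start < 0
  n_bad_coord <- sum(bad_coord)
  frags <- frags[!bad_coord]
  known <- frags$chrom %in% names(chrom_sizes)
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warning(n_unknown, " fragments on chromosomes absent from chrom_sizes dropped")
    frags <- frags[known]
  }
  over <- frags$end > chrom_sizes[frags$chrom]
  if (any(over)) {
    n_bad_coord <- n_bad_coord + sum(over)
    frags <- frags[!over]
  }
  len <- frags$end - frags$start
  keep <- len >= min_insert & len <= max_insert
  n_bad_insert <- sum(!keep)
  frags <- frags[keep]
  data.table::setorder(frags, barcode, chrom, start)
  structure(list(fragments = frags, chrom_sizes = chrom_sizes,
                 n_bad_coord = n_bad_coord, n_unknown_chrom = n_unknown,
                 n_bad_insert = n_bad_insert),
            class = "fragment_set")
}

#' @exportS3Method base::print
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "fragments,",
      length(unique(x$fragments$barcode)), "barcodes,",
      length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

# GRanges view of a fragment table (0-based half-open -> 1-based closed)
.frags_granges <- function(frags) {
  GenomicRanges::GRanges(frags$chrom,
                         IRanges::IRanges(start = frags$start + 1L, end = frags$end))
}

# BED data.frame/file -> GRanges
.bed_granges <- function(bed) {
  if (is.character(bed) && length(bed) == 1)
    bed <- data.table::fread(bed, header = FALSE)
  bed <- as.data.frame(bed)
  GenomicRanges::GRanges(as.character(bed[[1]]),
                         IRanges::IRanges(start = as.numeric(bed[[2]]) + 1L,
                                          end = as.numeric(bed[[3]])))
}

#' Barcode-level quality control
#'
#' Scores each barcode by its unique fragment count and its promoter
#' fraction (share of fragments overlapping an annotated promoter by at least
#' 1 bp). A barcode passes when the fragment count is *strictly* greater than
#' `min_fragments` and the promoter fraction lies within `promoter_range`
#' (inclusive).
#'
#' @param frags A `fragment_set`.
#' @param promoters Promoter intervals: BED file path or data.frame
#'   (chrom, start, end, ...).
#' @param min_fragments Minimum fragment count (exclusive bound).
#' @param promoter_range Inclusive promoter-fraction bounds.
#'
#' @return data.frame with one row per barcode: `barcode`, `n_fragments`,
#'   `promoter_fraction`, `passed`.
#' @export
qc_barcodes <- function(frags, promoters, min_fragments = 1000,
                        promoter_range = c(0.2, 0.8)) {
  stopifnot(inherits(frags, "fragment_set"))
  ft <- frags$fragments
  if (nrow(ft) == 0)
    return(data.frame(barcode = character(), n_fragments = integer(),
                      promoter_fraction = numeric(), passed = logical()))
  prom <- .bed_granges(promoters)
  gr <- .frags_granges(ft)
  in_prom <- IRanges::overlapsAny(gr, prom, minoverlap = 1L)
  dt <- data.table::data.table(barcode = ft$barcode, in_prom = in_prom)
  res <- dt[, list(n_fragments = .N, promoter_fraction = mean(in_prom)),
            by = "barcode"]
  res[, "passed" := res$n_fragments > min_fragments &
        res$promoter_fraction >= promoter_range[1] &
        res$promoter_fraction <= promoter_range[2]]
  as.data.frame(res)
}

#' Build the cell-by-bin count matrix
#'
#' Tiles every chromosome contiguously with `bin_size`-bp bins (last bin
#' truncated at the chromosome end) and counts, for each barcode in
#' `barcodes`, the fragments overlapping each bin by at least 1 bp. A
#' fragment spanning a bin boundary increments every bin it overlaps; with
#' `midpoint = TRUE` each fragment is instead assigned to the single bin
#' containing its midpoint.
#'
#' @param frags A `fragment_set`.
#' @param bin_size Bin width in bp.
#' @param barcodes Character vector of barcodes to keep (rows of the matrix,
#'   in this order). Defaults to all barcodes present.
#' @param midpoint Assign fragments by midpoint instead of overlap.
#'
#' @return A `cell_bin_counts`: list with `counts` (sparse integer
#'   cells x bins), `cell_barcodes`, `bin_coords` (data.frame
#'   chrom/start/end), `bin_size`.
#' @export
build_bin_matrix <- function(frags, bin_size = 5000, barcodes = NULL,
                             midpoint = FALSE) {
  stopifnot(inherits(frags, "fragment_set"), bin_size > 0)
  ft <- frags$fragments
  if (is.null(barcodes)) barcodes <- sort(unique(ft$barcode))
  missing_bc <- setdiff(barcodes, unique(ft$barcode))
  if (length(missing_bc))
    warning(length(missing_bc), " barcodes in pass-list have no fragments; zero rows emitted")
  chroms <- names(frags$chrom_sizes)
  n_bins_chr <- as.integer(ceiling(frags$chrom_sizes / bin_size))
  offset <- setNames(cumsum(c(0L, head(n_bins_chr, -1L))), chroms)
  bin_coords <- data.frame(
    chrom = rep(chroms, n_bins_chr),
    start = unlist(lapply(n_bins_chr, function(k) (seq_len(k) - 1))) * bin_size
  )
  bin_coords$end <- pmin(bin_coords$start + bin_size,
                         frags$chrom_sizes[bin_coords$chrom])
  m <- nrow(bin_coords)
  ft <- ft[ft$barcode %in% barcodes]
  cell_idx <- match(ft$barcode, barcodes)
  if (midpoint) {
    mid_bin <- (ft$start + ft$end) %/% 2L %/% bin_size
    i <- cell_idx
    j <- offset[ft$chrom] + mid_bin + 1L
  } else {
    first_bin <- ft$start %/% bin_size
    last_bin <- (ft$end - 1L) %/% bin_size # end exclusive
    span <- last_bin - first_bin + 1L
    i <- rep.int(cell_idx, span)
    j <- rep.int(offset[ft$chrom] + first_bin, span) +
      (sequence(span) - 1L) + 1L
  }
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1L,
                                 dims = c(length(barcodes), m))
  rownames(counts) <- barcodes
  structure(list(counts = counts, cell_barcodes = barcodes,
                 bin_coords = bin_coords, bin_size = bin_size),
            class = "cell_bin_counts")
}

#' Binarize a cell-by-bin count matrix
#'
#' The highest-count entries of the matrix — the top `top_fraction` of
#' non-zero elements, typically alignment artifacts — are zeroed
#' (`ceiling(nnz * top_fraction)` entries, largest counts first; ties at the
#' threshold count are kept in stable order), and all remaining non-zero
#' entries are set to 1. Per-cell coverage `C_i` and bin fraction
#' `P_i = C_i / m` are computed from the binarized matrix.
#'
#' @param counts A `cell_bin_counts` (or a bare sparse/dense count matrix).
#' @param top_fraction Fraction of non-zero entries to zero out, in `[0, 1)`.
#'
#' @return A `cell_bin_matrix`: list with binary sparse `X`, `coverage`
#'   (row sums), `p` (`coverage / ncol`), `bin_coords`, `bin_size`,
#'   `kept_bins` (all `TRUE` here; updated by [filter_bins()]).
#' @export
binarize <- function(counts, top_fraction = 0.001) {
  stopifnot(top_fraction >= 0, top_fraction < 1)
  if (inherits(counts, "cell_bin_counts")) {
    mat <- counts$counts
    bin_coords <- counts$bin_coords
    bin_size <- counts$bin_size
  } else {
    mat <- as(counts, "CsparseMatrix")
    bin_coords <- NULL
    bin_size <- NA_real_
  }
  mat <- as(as(as(mat, "dMatrix"), "CsparseMatrix"), "generalMatrix")
  nnz <- length(mat@x)
  if (nnz > 0) {
    n_zero <- if (top_fraction > 0) ceiling(nnz * top_fraction) else 0L
    if (n_zero > 0) {
      # largest counts first; order() is stable so ties keep storage order
      drop_idx <- order(mat@x, decreasing = TRUE)[seq_len(n_zero)]
      mat@x[drop_idx] <- 0
    }
    mat@x[mat@x > 0] <- 1
    mat <- Matrix::drop0(mat)
  }
  X <- as(mat, "CsparseMatrix")
  coverage <- Matrix::rowSums(X)
  structure(list(X = X, coverage = coverage, p = coverage / ncol(X),
                 bin_coords = bin_coords, bin_size = bin_size,
                 kept_bins = rep(TRUE, ncol(X))),
            class = "cell_bin_matrix")
}

#' @exportS3Method base::print
print.cell_bin_matrix <- function(x, ...) {
  cat("cell_bin_matrix:", nrow(x$X), "cells x", ncol(x$X), "bins;",
      "median coverage", stats::median(x$coverage), "\n")
  invisible(x)
}

#' Filter bins of a binary cell-by-bin matrix
#'
#' Removes, in order: bins overlapping `blacklist` intervals by at least
#' 1 bp; bins on `exclude_chroms` (sex chromosomes and chrM by default); and
#' — only when the mean per-cell fragment count is at least
#' `low_coverage_skip` — the `top_coverage_fraction` most covered of the
#' remaining bins (`floor(fraction * m_remaining)` columns), which are
#' invariant features. Low-coverage datasets skip the last step because bin
#' ranking there is noise-driven.
#'
#' @param x A `cell_bin_matrix` from [binarize()].
#' @param blacklist Optional BED path or data.frame of blacklisted intervals.
#' @param exclude_chroms Chromosome names to drop entirely.
#' @param top_coverage_fraction Fraction of top-coverage bins to remove.
#' @param low_coverage_skip Mean per-cell fragment count below which the
#'   coverage filter is skipped.
#'
#' @return The filtered `cell_bin_matrix`; `kept_bins` is a logical mask over
#'   the *original* bins and coverage/`p` are recomputed.
#' @export
filter_bins <- function(x, blacklist = NULL,
                        exclude_chroms = c("chrX", "chrY", "chrM"),
                        top_coverage_fraction = 0.05,
                        low_coverage_skip = 5000) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  m <- ncol(x$X)
  # local mask over current columns; folded into the original-bin mask below
  keep <- rep(TRUE, m)
  if (!is.null(x$bin_coords)) {
    if (!is.null(blacklist)) {
      bl <- .bed_granges(blacklist)
      bins_gr <- GenomicRanges::GRanges(
        x$bin_coords$chrom,
        IRanges::IRanges(start = x$bin_coords$start + 1L, end = x$bin_coords$end))
      keep <- keep & !IRanges::overlapsAny(bins_gr, bl, minoverlap = 1L)
    }
    keep <- keep & !(x$bin_coords$chrom %in% exclude_chroms)
  }
  mean_cov <- mean(Matrix::rowSums(x$X))
  if (mean_cov >= low_coverage_skip && top_coverage_fraction > 0) {
    col_cov <- Matrix::colSums(x$X)
    remaining <- which(keep)
    n_drop <- floor(top_coverage_fraction * length(remaining))
    if (n_drop > 0) {
      drop <- remaining[order(col_cov[remaining], decreasing = TRUE)[seq_len(n_drop)]]
      keep[drop] <- FALSE
    }
  }
  if (!any(keep)) stop("no features remain after bin filtering")
  X <- x$X[, keep, drop = FALSE]
  coverage <- Matrix::rowSums(X)
  global_keep <- x$kept_bins
  global_keep[which(global_keep)[!keep]] <- FALSE
  structure(list(X = X, coverage = coverage, p = coverage / ncol(X),
                 bin_coords = if (!is.null(x$bin_coords)) x$bin_coords[keep, , drop = FALSE] else NULL,
                 bin_size = x$bin_size,
                 kept_bins = global_keep),
            class = "cell_bin_matrix")
}

#' Drop zero-coverage cells
#'
#' The Jaccard kernel is undefined for cells without any accessible bin;
#' this removes them (with a message) before embedding.
#'
#' @param x A `cell_bin_matrix`.
#' @return The `cell_bin_matrix` restricted to cells with coverage `> 0`.
#' @export
drop_empty_cells <- function(x) {
  stopifnot(inherits(x, "cell_bin_matrix"))
  keep <- x$coverage > 0
  if (all(keep)) return(x)
  message(sum(!keep), " zero-coverage cells removed")
  x$X <- x$X[keep, , drop = FALSE]
  x$coverage <- x$coverage[keep]
  x$p <- x$p[keep]
  x
}
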