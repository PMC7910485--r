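#' Gene-body accessibility counts
#'
#' Counts, per cell and gene, the fragments overlapping the gene-body
#' interval by at least 1 bp; a fragment overlapping several (possibly
#' overlapping) genes is counted once for each.
#'
#' @param frags A `fragment_set`.
#' @param genes Gene intervals as a BED file path or data.frame; columns
#'   chrom, start, end and (optionally, column 4) gene id.
#' @param barcodes Barcodes forming the matrix rows (default: all present).
#' @return A sparse cells x genes count matrix with gene ids as column
#'   names.
#' @export
build_gene_matrix <- function(frags, genes, barcodes = NULL) {
  stopifnot(inherits(frags, "fragment_set"))
  if (is.character(genes) && length(genes) == 1)
    genes <- data.table::fread(genes, header = FALSE)
  genes <- as.data.frame(genes)
  if (nrow(genes) == 0) stop("empty gene set")
  gene_ids <- if (ncol(genes) >= 4) as.character(genes[[4]]) else
    sprintf("gene%d", seq_len(nrow(genes)))
  ft <- frags$fragments
  if (is.null(barcodes)) barcodes <- sort(unique(ft$barcode))
  gr_genes <- GenomicRanges::GRanges(
    as.character(genes[[1]]),
    IRanges::IRanges(start = as.numeric(genes[[2]]) + 1L, end = as.numeric(genes[[3]])))
  hits <- GenomicRanges::findOverlaps(.frags_granges(ft), gr_genes, minoverlap = 1L)
  cell_idx <- match(ft$barcode[S4Vectors::queryHits(hits)], barcodes)
  ok <- !is.na(cell_idx)
  G <- Matrix::sparseMatrix(i = cell_idx[ok],
                            j = S4Vectors::subjectHits(hits)[ok],
                            x = 1,
                            dims = c(length(barcodes), nrow(genes)))
  dimnames(G) <- list(barcodes, gene_ids)
  G
}

#' Counts-per-million normalization
#'
#' Scales every row to sum to one million; all-zero rows stay zero with a
#' warning.
#'
#' @param raw Cells x genes count matrix (sparse or dense).
#' @return Matrix of the same shape, rows summing to 1e6 (or 0).
#' @export
cpm <- function(raw) {
  rs <- Matrix::rowSums(raw)
  zero <- rs == 0
  if (any(zero)) warning(sum(zero), " cells without gene-overlapping fragments stay zero")
  scale <- ifelse(zero, 0, 1e6 / rs)
  if (is(raw, "sparseMatrix")) Matrix::Diagonal(x = scale) %*% raw
  else raw * scale
}

#' Markov diffusion smoothing of gene scores
#'
#' Smooths the normalized gene accessibility matrix over the cell-cell KNN
#' graph: the symmetrized adjacency gains unit self-loops, is row-normalized
#' into a Markov operator `A`, and the scores are propagated `t` steps,
#' each step replacing a cell's profile by the weighted average over its
#' neighborhood. `t = 0` returns the input unchanged.
#'
#' @param scores Cells x genes matrix (typically the [cpm()] output).
#' @param graph A `knn_graph` over the same cells (or an adjacency matrix).
#' @param t Number of diffusion steps.
#' @return Smoothed matrix of the same shape.
#' @export
diffuse_scores <- function(scores, graph, t = 3) {
  if (t < 0) stop("t must be non-negative")
  A <- .as_adjacency(graph)
  stopifnot(nrow(A) == nrow(scores))
  if (t == 0) return(scores)
  A <- A + Matrix::Diagonal(nrow(A)) # self-loop keeps each cell's own signal
  A <- Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
  out <- scores
  for (step in seq_len(t)) out <- A %*% out
  out <- if (is.matrix(scores)) as.matrix(out) else as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(scores)
  out
}
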