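#' Write a cell-by-bin matrix as MTX with side tables
#'
#' Writes `matrix.mtx` (MatrixMarket), `cells.tsv` (barcode plus any extra
#' per-cell columns), and `bins.tsv` (chrom, start, end) into `dir`.
#'
#' @param x A `cell_bin_matrix` or `cell_bin_counts`.
#' @param dir Output directory (created if missing).
#' @param cell_meta Optional data.frame of extra per-cell columns.
#' @return `dir`, invisibly.
#' @export
write_bin_matrix <- function(x, dir, cell_meta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- if (inherits(x, "cell_bin_matrix")) x$X else x$counts
  Matrix::writeMM(as(mat, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  cells <- data.frame(barcode = rownames(mat))
  if (!is.null(cell_meta)) cells <- cbind(cells, cell_meta)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bc <- if (inherits(x, "cell_bin_matrix")) x$bin_coords else x$bin_coords
  if (!is.null(bc))
    write.table(bc, file.path(dir, "bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell-by-bin matrix written by [write_bin_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `cells.tsv`, `bins.tsv`.
#' @param binary Binarize on read (any positive count becomes 1) and return
#'   a `cell_bin_matrix`; otherwise a `cell_bin_counts` is returned.
#' @return A `cell_bin_matrix` or `cell_bin_counts`.
#' @export
read_bin_matrix <- function(dir, binary = TRUE) {
  mat <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # writeMM stores all-ones matrices in pattern format; restore numeric 1s
  mat <- as(as(mat, "dMatrix"), "CsparseMatrix")
  cells <- read.table(file.path(dir, "cells.tsv"), sep = "\t", header = TRUE)
  rownames(mat) <- cells$barcode
  bins_path <- file.path(dir, "bins.tsv")
  bin_coords <- if (file.exists(bins_path))
    read.table(bins_path, sep = "\t", header = TRUE) else NULL
  bin_size <- if (!is.null(bin_coords) && nrow(bin_coords) > 0)
    bin_coords$end[1] - bin_coords$start[1] else NA_real_
  if (binary) {
    obj <- structure(list(counts = mat, cell_barcodes = cells$barcode,
                          bin_coords = bin_coords, bin_size = bin_size),
                     class = "cell_bin_counts")
    binarize(obj, top_fraction = 0)
  } else {
    structure(list(counts = mat, cell_barcodes = cells$barcode,
                   bin_coords = bin_coords, bin_size = bin_size),
              class = "cell_bin_counts")
  }
}

#' Write an embedding as TSV
#'
#' Writes `barcode, dim1..dimR` plus a side file of eigenvalues when the
#' object carries them.
#'
#' @param embedding A `spectral_embedding` or bare matrix.
#' @param path Output TSV path; eigenvalues go to `<path>.eigenvalues.tsv`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  U <- if (inherits(embedding, "spectral_embedding")) embedding$U else as.matrix(embedding)
  df <- data.frame(barcode = rownames(U) %||% seq_len(nrow(U)), U)
  names(df)[-1] <- sprintf("dim%d", seq_len(ncol(U)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(embedding, "spectral_embedding"))
    write.table(data.frame(eigenvalue = embedding$eigenvalues),
                paste0(path, ".eigenvalues.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
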