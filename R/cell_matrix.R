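#' Construct a cell-by-gene count matrix with metadata
#'
#' Carrier for single-cell RNA-seq counts: a sparse non-negative integer
#' matrix (cells in rows, genes in columns) plus per-cell metadata naming
#' the condition (`group`, `timepoint`) and, for synthetic data, the true
#' cell type.
#'
#' @param counts A matrix or `Matrix::sparseMatrix` of non-negative integer
#'   counts, cells x genes, with row and column names.
#' @param cell_meta A `data.frame` with one row per cell; must contain
#'   `cell_id`, `group`, `timepoint` (optionally `true_type`), in the same
#'   order as the rows of `counts`.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry cell (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("cell and gene names must be unique")
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(is.data.frame(cell_meta),
            all(c("cell_id", "group", "timepoint") %in% names(cell_meta)))
  if (nrow(cell_meta) != nrow(counts) ||
      !identical(as.character(cell_meta$cell_id), rownames(counts))) {
    stop("cell_meta rows must match counts rows (same cells, same order)")
  }
  structure(list(counts = counts, cell_meta = cell_meta), class = "cell_matrix")
}

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, %d nonzeros\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a count matrix from a MatrixMarket triplet
#'
#' Reads the on-disk dialect this package also writes: a MatrixMarket `.mtx`
#' file holding genes x cells (the orientation used by common single-cell
#' pipelines), a cells TSV (one barcode per line), a genes TSV (one gene id
#' per line), and a metadata TSV with header columns `cell_id`, `group`,
#' `timepoint` and optionally `true_type`. The matrix is transposed to the
#' internal cells x genes orientation.
#'
#' @param mtx_path,cells_path,genes_path,meta_path File paths.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(mtx_path, cells_path, genes_path, meta_path) {
  m <- Matrix::readMM(mtx_path)  # genes x cells on disk
  cells <- readLines(cells_path)
  genes <- readLines(genes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf(
      "shape mismatch: matrix is %d x %d but genes file has %d and cells file has %d entries",
      nrow(m), ncol(m), length(genes), length(cells)))
  }
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(meta) != length(cells)) {
    stop("metadata rows do not match the number of cells")
  }
  counts <- Matrix::t(m)
  dimnames(counts) <- list(cells, genes)
  cell_matrix(counts, meta)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Inverse of [read_cell_matrix()]; writes `matrix.mtx`, `barcodes.tsv`,
#' `genes.tsv` and `meta.tsv` under `dir`.
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "genes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
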