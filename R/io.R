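# Readers and writers for the package's standard plain-text formats:
# Matrix Market counts with gene/barcode sidecars, dense TSV counts,
# samples x genes bulk matrices and samples x types proportion tables.

#' Write a single-cell count dataset
#'
#' `format = "mtx"` writes `matrix.mtx` (Matrix Market, genes x cells),
#' `genes.tsv` (one gene per line) and `barcodes.tsv` (tab-separated
#' `barcode`, `cell_type`) into the directory `path`. `format = "tsv"`
#' writes a dense `counts.tsv` (genes x cells, gene ids in the first
#' column) and a `cells.tsv` sidecar with the cell-type labels.
#'
#' @param dataset A [cell_dataset()].
#' @param path Output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(dataset, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  barcodes <- data.frame(barcode = colnames(dataset$counts),
                         cell_type = dataset$cell_labels)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(dataset$gene_names, file.path(path, "genes.tsv"))
    write.table(barcodes, file.path(path, "barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    counts <- data.frame(gene = dataset$gene_names,
                         dataset$counts, check.names = FALSE)
    write.table(counts, file.path(path, "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(barcodes, file.path(path, "cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a single-cell count dataset written by [write_counts()]
#'
#' @param path Directory containing the files.
#' @param format `"mtx"` or `"tsv"`.
#' @param provenance Provenance tag for the dataset.
#' @return A [cell_dataset()].
#' @export
read_counts <- function(path, format = c("mtx", "tsv"), provenance = "sn") {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- readLines(file.path(path, "genes.tsv"))
    barcodes <- read.delim(file.path(path, "barcodes.tsv"),
                           stringsAsFactors = FALSE)
    if (length(genes) != nrow(m)) {
      stop("genes.tsv has ", length(genes), " genes but the matrix has ",
           nrow(m), " rows")
    }
    if (nrow(barcodes) != ncol(m)) {
      stop("barcodes.tsv has ", nrow(barcodes), " cells but the matrix has ",
           ncol(m), " columns")
    }
    rownames(m) <- genes
    colnames(m) <- barcodes$barcode
    labels <- barcodes$cell_type
  } else {
    counts <- read.delim(file.path(path, "counts.tsv"), check.names = FALSE,
                         stringsAsFactors = FALSE)
    genes <- counts[[1]]
    if (anyDuplicated(genes)) {
      stop("duplicated gene name(s): ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    }
    m <- as.matrix(counts[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in counts.tsv")
    rownames(m) <- genes
    barcodes <- read.delim(file.path(path, "cells.tsv"),
                           stringsAsFactors = FALSE)
    if (nrow(barcodes) != ncol(m)) {
      stop("cells.tsv does not match the number of count columns")
    }
    labels <- barcodes$cell_type
  }
  cell_dataset(m, labels, provenance = provenance)
}

#' Write / read a samples x genes expression matrix as TSV
#'
#' Header row carries the gene names; the first column the sample ids.
#'
#' @param m samples x genes matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_bulk_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(sample = rownames(m) %||% seq_len(nrow(m)),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk_matrix
#' @export
read_bulk_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a samples x types proportion matrix as CSV
#'
#' @param p samples x types matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_proportions <- function(p, path) {
  stopifnot(is.matrix(p))
  write.csv(data.frame(sample = rownames(p) %||% seq_len(nrow(p)), p,
                       check.names = FALSE),
            path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
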