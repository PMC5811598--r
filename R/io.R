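# Count-matrix serialisation: MatrixMarket triplets with row/column label
# files (the single-cell convention), plus a dense TSV alternative.

#' Write a count matrix
#'
#' `format = "mtx"` writes `matrix.mtx`, `barcodes.tsv` and `features.tsv`
#' into `dir`; `format = "tsv"` writes a single dense `counts.tsv` with
#' barcodes as row names.
#'
#' @param matrix A cell x feature integer matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param format `"mtx"` or `"tsv"`.
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(matrix, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    m <- Matrix::Matrix(matrix, sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(rownames(matrix), file.path(dir, "barcodes.tsv"))
    writeLines(colnames(matrix), file.path(dir, "features.tsv"))
    kind <- attr(matrix, "feature_kind")
    if (!is.null(kind)) writeLines(kind, file.path(dir, "feature_kind.txt"))
  } else {
    utils::write.table(matrix, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix]
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` (and optionally `feature_kind.txt`).
#' @return A dense integer matrix with dimnames and `feature_kind`.
#' @export
read_count_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.tsv")),
                      readLines(file.path(dir, "features.tsv")))
  kind_file <- file.path(dir, "feature_kind.txt")
  if (file.exists(kind_file)) attr(m, "feature_kind") <- readLines(kind_file)
  m
}
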