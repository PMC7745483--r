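#' Write a matrix as dense TSV or sparse MatrixMarket
#'
#' Dense TSV keeps dimnames in the file; the MatrixMarket variant writes the
#' sparse pattern plus a `<path>.labels` sidecar with one row label per line.
#'
#' @param M Numeric matrix.
#' @param path Output path; a `.mtx` extension selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(M) %||% as.character(seq_len(nrow(M))),
               paste0(path, ".labels"))
  } else {
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       row.names = !is.null(rownames(M)),
                       col.names = !is.null(colnames(M)))
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path `.mtx` or TSV path.
#' @return Base dense matrix with row labels restored when available.
#' @export
read_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    M <- as.matrix(Matrix::readMM(path))
    lab <- paste0(path, ".labels")
    if (file.exists(lab)) rownames(M) <- readLines(lab)
    M
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
  }
}

#' Write an embedding matrix as TSV with a node-id column
#'
#' @param E Embedding matrix with rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(E, path) {
  df <- data.frame(node_id = rownames(E) %||% as.character(seq_len(nrow(E))),
                   E, check.names = FALSE)
  colnames(df) <- c("node_id", paste0("e", seq_len(ncol(E))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
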