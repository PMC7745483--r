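#' Pair feature vectors from a node embedding matrix
#'
#' The feature vector of the pair (lncRNA `i`, miRNA `j`) is the
#' concatenation of the two node embeddings, `[E[i, ]; E[r + j, ]]`, width
#' `2 * ncol(E)`.
#'
#' @param E `(r+t) x dim` embedding matrix (lncRNA rows first).
#' @param pairs Data frame with 1-based columns `i` (lncRNA index) and `j`
#'   (miRNA index).
#' @param r Number of lncRNAs.
#' @return `nrow(pairs) x 2*dim` feature matrix.
#' @export
pair_features <- function(E, pairs, r) {
  t_ <- nrow(E) - r
  assert_that(all(pairs$i >= 1 & pairs$i <= r), "lncRNA index out of range")
  assert_that(all(pairs$j >= 1 & pairs$j <= t_), "miRNA index out of range")
  F_ <- cbind(E[pairs$i, , drop = FALSE], E[r + pairs$j, , drop = FALSE])
  colnames(F_) <- c(paste0("l", seq_len(ncol(E))), paste0("m", seq_len(ncol(E))))
  rownames(F_) <- NULL
  F_
}

#' Enumerate the full lncRNA x miRNA pair grid with labels
#'
#' @param A Binary interaction matrix.
#' @return Tibble with columns `i`, `j`, `label` in column-major grid order.
#' @export
pair_grid <- function(A) {
  tibble::tibble(i = rep(seq_len(nrow(A)), ncol(A)),
                 j = rep(seq_len(ncol(A)), each = nrow(A)),
                 label = as.integer(A))
}
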