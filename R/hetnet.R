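#' Assemble the heterogeneous lncRNA-miRNA network
#'
#' Builds the `(r+t) x (r+t)` block matrix
#' `H = [[W_l, A], [t(A), W_m]]`: lncRNA similarity graph and miRNA
#' similarity graph on the diagonal, the bipartite interaction matrix off the
#' diagonal. Similarity blocks keep their real-valued weights and the
#' interaction block keeps unit weights; no rescaling between blocks. Node
#' order is lncRNAs first (input order), then miRNAs, for every artifact of
#' the pipeline.
#'
#' @param W_l `r` x `r` lncRNA neighbor graph ([topk_neighbor_graph()]).
#' @param A `r` x `t` binary interaction matrix.
#' @param W_m `t x t` miRNA neighbor graph.
#' @return Object of class `hetnet`: list with the matrix `H`, sizes `r`,
#'   `t`, and node ids.
#' @examples
#' hn <- assemble_hetnet(matrix(0, 1, 1), matrix(1, 1, 1), matrix(0, 1, 1))
#' hn$H
#' @export
assemble_hetnet <- function(W_l, A, W_m) {
  r <- nrow(A); t_ <- ncol(A)
  assert_that(nrow(W_l) == r && ncol(W_l) == r,
              sprintf("W_l must be %d x %d to conform with A", r, r))
  assert_that(nrow(W_m) == t_ && ncol(W_m) == t_,
              sprintf("W_m must be %d x %d to conform with A", t_, t_))
  H <- rbind(cbind(W_l, A), cbind(t(A), W_m))
  lnc_ids <- rownames(A) %||% sprintf("lnc%03d", seq_len(r))
  mir_ids <- colnames(A) %||% sprintf("mir%03d", seq_len(t_))
  dimnames(H) <- list(c(lnc_ids, mir_ids), c(lnc_ids, mir_ids))
  structure(list(H = H, r = r, t = t_,
                 lncrna_ids = lnc_ids, mirna_ids = mir_ids),
            class = "hetnet")
}

#' @exportS3Method base::print
print.hetnet <- function(x, ...) {
  cat(sprintf("<hetnet> %d lncRNAs + %d miRNAs, %d nonzero entries\n",
              x$r, x$t, sum(x$H != 0)))
  invisible(x)
}

#' Split a heterogeneous network back into its blocks
#'
#' Inverse of [assemble_hetnet()]: returns the similarity blocks and the
#' interaction matrix bit-identically.
#'
#' @param hn A `hetnet` object.
#' @return List with `W_l`, `A`, `W_m`.
#' @export
split_hetnet <- function(hn) {
  stopifnot(inherits(hn, "hetnet"))
  il <- seq_len(hn$r); im <- hn$r + seq_len(hn$t)
  list(W_l = hn$H[il, il, drop = FALSE],
       A = hn$H[il, im, drop = FALSE],
       W_m = hn$H[im, im, drop = FALSE])
}

#' Randomly mask known interactions
#'
#' Flips exactly `round(fraction * nnz(A))` ones of `A` to zero, chosen
#' uniformly without replacement, and returns the removed edges. Used both to
#' hide test-fold positives from the network before embedding and for the
#' network-sparsity robustness experiment (removal ratios 0.1-0.4).
#'
#' @param A Binary interaction matrix.
#' @param fraction Fraction of known links to remove, in `[0, 1)`.
#' @param seed Integer seed; the mask is deterministic given it.
#' @return List with `A_masked` and `removed` (tibble `i`, `j`,
#'   `lncrna_id`, `mirna_id`).
#' @export
mask_interactions <- function(A, fraction, seed = 1L) {
  assert_that(fraction >= 0 && fraction < 1, "fraction must be in [0, 1)")
  ones <- which(A == 1L)
  n_remove <- round(fraction * length(ones))
  if (fraction > 0) {
    assert_that(n_remove >= 1,
                "fraction * nnz(A) rounds to zero edges; nothing to remove")
  }
  A_masked <- A
  removed_idx <- integer(0)
  if (n_remove > 0) {
    removed_idx <- with_seed(derive_seed(seed, 0L),
                             sample(ones, n_remove, replace = FALSE))
    A_masked[removed_idx] <- 0L
  }
  rc <- arrayInd(removed_idx, dim(A))
  removed <- tibble::tibble(
    i = rc[, 1], j = rc[, 2],
    lncrna_id = (rownames(A) %||% as.character(seq_len(nrow(A))))[rc[, 1]],
    mirna_id = (colnames(A) %||% as.character(seq_len(ncol(A))))[rc[, 2]])
  list(A_masked = A_masked, removed = removed)
}
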