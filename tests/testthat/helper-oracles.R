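# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: naive scans, exhaustive enumeration, grid
# search and hand-rolled algebra only.

# naive overlapping substring scan for k-mer counts, lexicographic ACGU order
oracle_kmer_counts <- function(residues, k) {
  bases <- c("A", "C", "G", "U")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), k))[, k:1, drop = FALSE])
  kmers <- sort(kmers)
  counts <- setNames(integer(length(kmers)), kmers)
  for (s in seq_len(nchar(residues) - k + 1)) {
    w <- substr(residues, s, s + k - 1)
    counts[w] <- counts[w] + 1L
  }
  counts
}

# grid search over the simplex for the ridge reconstruction weights
oracle_simplex_weights <- function(G, x, lambda, step = 1e-3) {
  k <- ncol(G)
  stopifnot(k == 2)  # fine-grained grid is only tractable for 2 neighbors
  w1 <- seq(0, 1, by = step)
  obj <- vapply(w1, function(w) {
    wv <- c(w, 1 - w)
    sum((x - G %*% wv)^2) + lambda * sum(wv^2)
  }, 0)
  best <- w1[which.min(obj)]
  c(best, 1 - best)
}

# exhaustive positive-negative pair concordance (ties count 1/2)
oracle_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent step-curve integration of the precision-recall curve
oracle_aupr_step <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  prev_r <- 0; area <- 0
  for (idx in seq_along(y)) {
    if (y[idx] == 1) {
      area <- area + (recall[idx] - prev_r) * precision[idx]
      prev_r <- recall[idx]
    }
  }
  area
}

# cosine similarity matrix between rows
row_cosine <- function(X) {
  Xn <- X / sqrt(rowSums(X^2))
  tcrossprod(Xn)
}

# small connected weighted graph for embedding tests
toy_graph <- function(n = 10, seed = 1) {
  set.seed(seed)
  repeat {
    H <- matrix(0, n, n)
    H[upper.tri(H)] <- rbinom(n * (n - 1) / 2, 1, 0.35) * runif(n * (n - 1) / 2, 0.2, 1)
    H <- H + t(H)
    if (all(rowSums(H) > 0) && emblink:::n_components(H) == 1) return(H)
  }
}

# two disconnected cliques (for separation checks)
two_cliques <- function(m = 6) {
  H <- matrix(0, 2 * m, 2 * m)
  H[seq_len(m), seq_len(m)] <- 1
  H[m + seq_len(m), m + seq_len(m)] <- 1
  diag(H) <- 0
  H
}

small_dataset <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_lncrna = 18L, n_mirna = 9L, n_blocks = 3L,
         lncrna_len_range = c(60L, 90L),
         within_block_link_prob = 0.6, cross_block_link_prob = 0.05,
         seed = seed),
    list(...))
  simulate_lmi_data(do.call(lmi_sim_spec, args))
}
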