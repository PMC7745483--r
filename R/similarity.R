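#' k-mer spectrum features for a table of sequences
#'
#' Counts every overlapping length-`k` word of each sequence over the
#' A/C/G/U alphabet, in lexicographic k-mer order. The row sums equal
#' `nchar(residues) - k + 1` by construction. The default `k = 5` is the
#' 5-spectrum used throughout the pipeline.
#'
#' @param sequences Tibble with `id` and `residues` columns (see
#'   [read_fasta()]).
#' @param k Word length.
#' @return Integer matrix of dimension `n x 4^k`, rownames = ids, colnames =
#'   k-mers.
#' @examples
#' s <- tibble::tibble(id = "x", residues = "ACGUA")
#' rowSums(kmer_spectra(s, k = 2))  # 4 windows
#' @export
kmer_spectra <- function(sequences, k = 5L) {
  assert_that(k >= 1, "k must be positive")
  short <- sequences$id[nchar(sequences$residues) < k]
  assert_that(length(short) == 0,
              paste0("sequences shorter than k = ", k, ": ",
                     paste(short, collapse = ", ")))
  set <- Biostrings::RNAStringSet(setNames(sequences$residues, sequences$id))
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  rownames(counts) <- sequences$id
  storage.mode(counts) <- "integer"
  counts
}

#' Ridge-regularized least squares on the probability simplex
#'
#' Solves `min_w ||x - G w||^2 + lambda ||w||^2` subject to `w >= 0`,
#' `sum(w) = 1` by a Lawson-Hanson style active-set iteration on the KKT
#' system. Exact (to solver precision) for these small strictly convex
#' problems; used per-entity by [lns_similarity()].
#'
#' @param G Feature matrix with one column per neighbor.
#' @param x Target feature vector.
#' @param lambda Nonnegative ridge penalty.
#' @return Weight vector on the simplex.
#' @export
simplex_ridge_ls <- function(G, x, lambda = 1e-6) {
  kk <- ncol(G)
  if (kk == 1L) return(1)
  Hm <- crossprod(G) + diag(lambda, kk)
  cv <- as.numeric(crossprod(G, x))

  solve_eq <- function(P) {
    # equality-constrained minimizer restricted to the passive set P
    m <- sum(P)
    K <- rbind(cbind(2 * Hm[P, P, drop = FALSE], rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * cv[P], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol) || any(!is.finite(sol))) {
      sol <- c(rep(1 / m, m), 0)  # degenerate (e.g. identical columns)
    }
    w <- numeric(kk)
    w[P] <- sol[seq_len(m)]
    w
  }

  tol <- 1e-10
  P <- rep(TRUE, kk)
  w <- rep(1 / kk, kk)
  for (iter in seq_len(4L * kk)) {
    w_new <- solve_eq(P)
    if (any(w_new[P] < -tol)) {
      # step from the feasible w toward w_new until a variable hits zero
      d <- w_new - w
      blocking <- which(P & w_new < -tol)
      alpha <- min(w[blocking] / (w[blocking] - w_new[blocking]))
      w <- w + alpha * d
      out <- blocking[which.min(w[blocking] / pmax(1e-300, w[blocking] - w_new[blocking]))]
      w[out] <- 0
      P[out] <- FALSE
      if (!any(P)) { P[which.max(cv)] <- TRUE }
      next
    }
    w <- pmax(w_new, 0)
    # KKT check for the zeroed variables: gradient + mu must be >= 0
    g <- 2 * (Hm %*% w - cv)
    mu <- -mean(g[P])
    viol <- which(!P & (g + mu) < -1e-8)
    if (length(viol) == 0) break
    P[viol[which.min((g + mu)[viol])]] <- TRUE
  }
  w / sum(w)
}

#' Linear-neighborhood similarity from k-mer spectra
#'
#' For each entity, the spectra are L2-normalized (removing the length
#' disparity between lncRNAs and miRNAs) and the entity's feature vector is
#' reconstructed from its `kappa` Euclidean-nearest neighbors by
#' nonnegative, unit-sum weights ([simplex_ridge_ls()]). The weights become
#' the similarity row: `S[i, j]` is the reconstruction weight of neighbor `j`
#' (zero outside the neighborhood), so every row of `S` is a probability
#' vector and the diagonal is zero.
#'
#' @param spectra Count matrix from [kmer_spectra()] (rows = entities).
#' @param kappa Reconstruction neighborhood size (must be `< n`).
#' @param lambda Ridge penalty stabilizing the per-row solve.
#' @return `n x n` similarity matrix with the input rownames.
#' @export
lns_similarity <- function(spectra, kappa = 10L, lambda = 1e-6) {
  n <- nrow(spectra)
  assert_that(n >= 2, "need at least 2 entities")
  assert_that(kappa >= 1 && kappa < n, "kappa must satisfy 1 <= kappa < n")
  X <- spectra / sqrt(rowSums(spectra^2))
  D2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * tcrossprod(X)
  S <- matrix(0, n, n, dimnames = list(rownames(spectra), rownames(spectra)))
  for (i in seq_len(n)) {
    d <- D2[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(kappa)]  # ties -> lower index
    w <- simplex_ridge_ls(t(X[nb, , drop = FALSE]), X[i, ], lambda)
    if (anyNA(w) || any(!is.finite(w))) w <- rep(1 / kappa, kappa)
    S[i, nb] <- w
  }
  attr(S, "kappa") <- kappa
  attr(S, "lambda") <- lambda
  S
}

#' Sparsify a similarity matrix to a top-k neighbor graph
#'
#' Keeps, per row, the `n_neighbors` largest off-diagonal similarities (ties
#' broken toward the lower column index) and then symmetrizes by elementwise
#' maximum with the transpose, yielding an undirected weighted kNN graph.
#'
#' @param S Square similarity matrix (zero diagonal assumed meaningful).
#' @param n_neighbors Neighbors kept per row before symmetrization
#'   (default 10, the construction used for both entity kinds).
#' @param symmetrize If `FALSE`, return the row-wise sparsified matrix
#'   without the max-symmetrization.
#' @return Nonnegative matrix `W` with zero diagonal; symmetric when
#'   `symmetrize = TRUE`.
#' @export
topk_neighbor_graph <- function(S, n_neighbors = 10L, symmetrize = TRUE) {
  n <- nrow(S)
  assert_that(n_neighbors >= 1, "n_neighbors must be >= 1")
  if (n_neighbors >= n) {
    warning("n_neighbors >= number of entities; keeping all off-diagonal entries")
    n_neighbors <- n - 1L
  }
  W <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    keep <- order(-s, seq_len(n))[seq_len(n_neighbors)]
    W[i, keep] <- S[i, keep]
  }
  diag(W) <- 0
  if (symmetrize) W <- pmax(W, t(W))
  W
}
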