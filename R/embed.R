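#' Learn node embeddings of a heterogeneous network
#'
#' Dispatcher over the five embedding algorithms used by the ensemble:
#' Laplacian eigenmaps (`"le"`), GraRep (`"grarep"`), HOPE (`"hope"`),
#' DeepWalk (`"deepwalk"`) and the (variational) graph autoencoder
#' (`"gae"`). All methods return an `(r+t) x dim` matrix whose rows follow
#' the node order of `H` (lncRNAs first, then miRNAs).
#'
#' @param H Symmetric nonnegative adjacency matrix (or a `hetnet` object).
#' @param method One of `"le"`, `"grarep"`, `"hope"`, `"deepwalk"`, `"gae"`.
#' @param dim Embedding dimension (default 120).
#' @param ... Method-specific arguments, see [embed_le()], [embed_grarep()],
#'   [embed_hope()], [embed_deepwalk()], [embed_gae()].
#' @return Numeric embedding matrix with a `method` attribute.
#' @export
embed_graph <- function(H, method = c("le", "grarep", "hope", "deepwalk", "gae"),
                        dim = 120L, ...) {
  method <- match.arg(method)
  if (inherits(H, "hetnet")) H <- H$H
  E <- switch(method,
    le = embed_le(H, dim, ...),
    grarep = embed_grarep(H, dim, ...),
    hope = embed_hope(H, dim, ...),
    deepwalk = embed_deepwalk(H, dim, ...),
    gae = embed_gae(H, dim, ...))
  attr(E, "method") <- method
  E
}

#' Laplacian eigenmaps embedding
#'
#' Solves the generalized eigenproblem `L v = lambda D v` with `L = D - H`
#' and returns the eigenvectors of the `dim` smallest nonzero eigenvalues in
#' ascending order. The constant eigenvector (eigenvalue 0) is excluded;
#' returned columns satisfy `t(v) D v = 1` and `t(v) D 1 = 0`. Computed via
#' the symmetric-normalized Laplacian, so a dense symmetric eigensolver
#' suffices.
#'
#' @param H Symmetric nonnegative adjacency matrix; every node must have
#'   positive degree.
#' @param dim Number of eigenvector columns.
#' @param zero_tol Eigenvalues below this are treated as the null space
#'   (one per connected component).
#' @return `n x dim` matrix.
#' @export
embed_le <- function(H, dim = 120L, zero_tol = 1e-9) {
  if (inherits(H, "hetnet")) H <- H$H
  check_adjacency(H)
  deg <- rowSums(H)
  assert_that(all(deg > 0), "graph has zero-degree nodes; cannot form the Laplacian pencil")
  if (n_components(H) > 1L) {
    warning("graph has multiple connected components; embedding them jointly")
  }
  dhalf <- 1 / sqrt(deg)
  Lsym <- diag(nrow(H)) - (dhalf * H) * rep(dhalf, each = nrow(H))
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  vals <- rev(eig$values)              # ascending
  vecs <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  nonzero <- which(vals > zero_tol)
  assert_that(length(nonzero) >= dim,
              sprintf("dim = %d exceeds the %d available nonzero eigenvalues",
                      dim, length(nonzero)))
  sel <- nonzero[seq_len(dim)]
  E <- vecs[, sel, drop = FALSE] * dhalf  # back-transform: v = D^{-1/2} u
  rownames(E) <- rownames(H)
  attr(E, "eigenvalues") <- vals[sel]
  E
}

#' GraRep embedding
#'
#' For each step `s = 1..k_step`, forms the transition matrix
#' `P = D^{-1} H`, takes the positive log transition statistics
#' `X_s = max(log(P^s_ij / colsum_j(P^s)) + log(n), 0)` and embeds by the
#' rank-`dim/k_step` truncated SVD `U sqrt(Sigma)`; the per-step blocks are
#' concatenated. `k_step = 1` is the pipeline default.
#'
#' @param H Symmetric nonnegative adjacency; zero-degree nodes are an error
#'   (the transition matrix is undefined).
#' @param dim Total embedding dimension; must be divisible by `k_step`.
#' @param k_step Highest transition power used (1-4).
#' @return `n x dim` matrix.
#' @export
embed_grarep <- function(H, dim = 120L, k_step = 1L) {
  if (inherits(H, "hetnet")) H <- H$H
  check_adjacency(H)
  assert_that(k_step >= 1 && k_step <= 4, "k_step must be in 1..4")
  assert_that(dim %% k_step == 0, "dim must be divisible by k_step")
  deg <- rowSums(H)
  assert_that(all(deg > 0), "graph has zero-degree nodes; transition matrix undefined")
  n <- nrow(H)
  P <- H / deg
  Ps <- diag(n)
  d_sub <- dim %/% k_step
  blocks <- vector("list", k_step)
  for (s in seq_len(k_step)) {
    Ps <- Ps %*% P
    colsum <- colSums(Ps)
    X <- log(Ps) - rep(log(colsum), each = n) + log(n)
    X[Ps == 0] <- 0
    X[X < 0] <- 0
    sv <- svd(X, nu = d_sub, nv = 0)
    blocks[[s]] <- sv$u * rep(sqrt(sv$d[seq_len(d_sub)]), each = n)
  }
  E <- do.call(cbind, blocks)
  rownames(E) <- rownames(H)
  E
}

#' HOPE embedding (Katz proximity factorization)
#'
#' Factorizes the Katz proximity
#' `S = (I - b H)^{-1} (b H)` by a rank-`dim/2` truncated SVD and
#' concatenates the source (`U sqrt(Sigma)`) and target (`V sqrt(Sigma)`)
#' embeddings. The decay `b` must satisfy `b < 1/rho(H)` for the Neumann
#' series to converge; the default is half that bound.
#'
#' @param H Symmetric nonnegative adjacency matrix.
#' @param dim Total embedding dimension (even; `dim/2` singular pairs).
#' @param katz_decay Decay factor `b`; `NULL` for `0.5 / rho(H)`.
#' @return `n x dim` matrix with attribute `katz_decay`.
#' @export
embed_hope <- function(H, dim = 120L, katz_decay = NULL) {
  if (inherits(H, "hetnet")) H <- H$H
  check_adjacency(H)
  assert_that(dim %% 2 == 0, "dim must be even (source/target halves)")
  rho <- max(abs(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values))
  if (is.null(katz_decay)) katz_decay <- if (rho > 0) 0.5 / rho else 0.5
  assert_that(rho == 0 || katz_decay < 1 / rho,
              sprintf("katz_decay must be < 1/spectral_radius(H) = %.6g", 1 / rho))
  n <- nrow(H)
  S <- solve(diag(n) - katz_decay * H, katz_decay * H)
  d_sub <- dim %/% 2
  sv <- svd(S, nu = d_sub, nv = d_sub)
  scale <- rep(sqrt(sv$d[seq_len(d_sub)]), each = n)
  E <- cbind(sv$u * scale, sv$v * scale)
  rownames(E) <- rownames(H)
  attr(E, "katz_decay") <- katz_decay
  E
}

#' Truncated random walks over a weighted graph
#'
#' Starts `walks_per_node` walks of length `walk_length` from every node
#' (freshly shuffled start order per pass); transition probabilities are the
#' row-normalized edge weights of `H`. Isolated nodes produce walks that
#' repeat the node itself.
#'
#' @param H Symmetric nonnegative adjacency matrix.
#' @param walk_length Nodes per walk (default 80).
#' @param walks_per_node Walks started from each node (default 30).
#' @param seed Integer seed; the corpus is deterministic given it.
#' @return Integer matrix of walks (`n * walks_per_node` rows,
#'   `walk_length` columns, 1-based node indices).
#' @export
random_walks <- function(H, walk_length = 80L, walks_per_node = 30L, seed = 1L) {
  if (inherits(H, "hetnet")) H <- H$H
  check_adjacency(H)
  n <- nrow(H)
  neighbors <- vector("list", n)
  cumprobs <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(H[i, ] > 0)
    neighbors[[i]] <- as.integer(nb)
    w <- H[i, nb]
    cumprobs[[i]] <- if (length(nb)) cumsum(w) / sum(w) else numeric(0)
  }
  cpp_random_walks(neighbors, cumprobs, as.integer(walks_per_node),
                   as.integer(walk_length), as.numeric(seed))
}

#' DeepWalk embedding
#'
#' Generates a corpus of truncated random walks ([random_walks()]) and trains
#' skip-gram with negative sampling on it (walks as sentences, nodes as
#' words, dynamic window). Defaults follow the study settings: walk length
#' 80, 30 walks per node, window 30; 5 negative samples and 5 passes over the
#' corpus.
#'
#' @param H Symmetric nonnegative adjacency matrix.
#' @param dim Embedding dimension.
#' @param walk_length,walks_per_node,window Walk corpus and context
#'   parameters.
#' @param negative Negative samples per positive context pair.
#' @param epochs Passes over the walk corpus.
#' @param learning_rate Initial SGD learning rate (linearly decayed).
#' @param seed Integer seed for the walk corpus and the SGD schedule.
#' @return `n x dim` matrix.
#' @export
embed_deepwalk <- function(H, dim = 120L, walk_length = 80L,
                           walks_per_node = 30L, window = 30L,
                           negative = 5L, epochs = 5L,
                           learning_rate = 0.025, seed = 1L) {
  if (inherits(H, "hetnet")) H <- H$H
  walks <- random_walks(H, walk_length, walks_per_node,
                        seed = derive_seed(seed, 0L))
  E <- cpp_sgns(walks, nrow(H), as.integer(dim), as.integer(window),
                as.integer(negative), as.integer(epochs),
                as.numeric(learning_rate), as.numeric(derive_seed(seed, 1L)))
  rownames(E) <- rownames(H)
  E
}
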