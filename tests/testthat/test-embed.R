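# Spectral identities and factorization optimality are checked against dense
# linear-algebra oracles computed independently inside the tests.

test_that("Laplacian eigenmaps solve the generalized pencil on a path graph", {
  H <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, byrow = TRUE)
  # dense oracle for the pencil L v = lambda D v
  D <- diag(rowSums(H))
  vals <- sort(Re(eigen(solve(D, D - H))$values))
  expect_equal(vals, c(0, 1, 2), tolerance = 1e-12)

  E <- embed_le(H, dim = 1)
  expect_equal(attr(E, "eigenvalues"), 1, tolerance = 1e-10)
  v <- E[, 1]
  expect_equal(sum(v * rowSums(H) * v), 1, tolerance = 1e-6)   # v' D v = 1
  expect_equal(sum(v * rowSums(H)), 0, tolerance = 1e-6)       # v' D 1 = 0
})

test_that("LE columns are D-orthonormal and exclude the constant vector", {
  H <- toy_graph(12, seed = 2)
  E <- embed_le(H, dim = 4)
  D <- rowSums(H)
  G <- t(E) %*% (D * E)
  expect_equal(unname(G), diag(4), tolerance = 1e-6)
  expect_equal(unname(colSums(D * E)), rep(0, 4), tolerance = 1e-6)
  expect_error(embed_le(H, dim = 12), "nonzero eigenvalues")
  expect_warning(embed_le(two_cliques(4), dim = 2), "components")
})

test_that("GraRep factorization is the optimal truncated SVD of the log statistics", {
  H <- toy_graph(20, seed = 3)
  d <- 4
  E <- embed_grarep(H, dim = d, k_step = 1)
  # independent reconstruction of the positive log transition statistics
  P <- H / rowSums(H)
  n <- nrow(H)
  X <- log(P) - rep(log(colSums(P)), each = n) + log(n)
  X[P == 0] <- 0
  X[X < 0] <- 0
  sv <- svd(X)
  G_oracle <- sv$u[, 1:d] %*% diag(sv$d[1:d]) %*% t(sv$u[, 1:d])
  expect_equal(E %*% t(E), G_oracle, tolerance = 1e-8)
  expect_error(embed_grarep(H, dim = 5, k_step = 2), "divisible")
})

test_that("GraRep embeddings are permutation-equivariant", {
  H <- toy_graph(10, seed = 4)
  perm <- c(3, 1, 4, 2, 6, 5, 9, 10, 7, 8)
  E1 <- embed_grarep(H, dim = 4)
  E2 <- embed_grarep(H[perm, perm], dim = 4)
  # Gram matrices are invariant to the sign/rotation ambiguity of the SVD
  expect_equal(E2 %*% t(E2), (E1 %*% t(E1))[perm, perm], tolerance = 1e-6)
})

test_that("HOPE reproduces the closed-form Katz matrix of a single edge", {
  H <- matrix(c(0, 1, 1, 0), 2)
  b <- 0.4
  E <- embed_hope(H, dim = 4, katz_decay = b)  # full-rank factorization
  Es <- E[, 1:2]; Et <- E[, 3:4]
  katz <- matrix(c(b^2, b, b, b^2), 2) / (1 - b^2)
  expect_equal(Es %*% t(Et), katz, tolerance = 1e-8)
  # degenerate decay gives a zero embedding
  expect_equal(unname(embed_hope(H, dim = 2, katz_decay = 0)),
               matrix(0, 2, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(embed_hope(H, dim = 2, katz_decay = 1.5), "spectral_radius")
})

test_that("HOPE reconstruction error equals the optimal rank truncation", {
  H <- toy_graph(24, seed = 5)
  d <- 6
  E <- embed_hope(H, dim = 2 * d)
  b <- attr(E, "katz_decay")
  katz <- solve(diag(nrow(H)) - b * H, b * H)
  sv <- svd(katz)
  optimal_err <- sqrt(sum(sv$d[-(1:d)]^2))
  recon <- E[, 1:d] %*% t(E[, d + 1:d])
  expect_equal(sqrt(sum((katz - recon)^2)), optimal_err, tolerance = 1e-8)
})

test_that("random walk corpus matches the requested shape and edge set", {
  H <- toy_graph(12, seed = 6)
  walks <- random_walks(H, walk_length = 15, walks_per_node = 4, seed = 9)
  expect_equal(dim(walks), c(12 * 4, 15))
  expect_equal(as.integer(table(walks[, 1])), rep(4L, 12))  # 4 starts per node
  for (row in seq_len(nrow(walks))) {
    steps <- cbind(walks[row, -ncol(walks)], walks[row, -1])
    expect_true(all(H[steps] > 0))
  }
  expect_identical(walks, random_walks(H, 15, 4, seed = 9))
})

test_that("DeepWalk separates two disconnected cliques", {
  H <- two_cliques(6)
  gap <- vapply(1:5, function(sd) {
    E <- embed_deepwalk(H, dim = 4, walk_length = 20, walks_per_node = 8,
                        window = 3, epochs = 3, seed = sd)
    cs <- row_cosine(E)
    same <- outer(rep(1:2, each = 6), rep(1:2, each = 6), `==`)
    diag(same) <- NA
    mean(cs[same & !is.na(same)]) - mean(cs[!same & !is.na(same)])
  }, 0)
  expect_gt(mean(gap), 0)
})

test_that("GAE training reduces the loss and reconstructs planted edges", {
  ds <- simulate_lmi_data(lmi_sim_spec(seed = 12))  # standard planted fixture
  graphs <- similarity_graphs(ds)
  hn <- assemble_hetnet(graphs$W_l, ds$A, graphs$W_m)
  aucs <- vapply(1:5, function(sd) {
    E <- embed_gae(hn$H, dim = 12, hidden = 64, epochs = 200, seed = sd)
    expect_lt(attr(E, "recon_final"), attr(E, "recon_initial"))
    S <- E %*% t(E)
    off <- upper.tri(S)
    oracle_auc_concordance(S[off], (hn$H[off] > 0) + 0)
  }, 0)
  expect_gt(mean(aucs), 0.8)
})

test_that("embeddings are finite with the expected shape on fixture graphs", {
  ds <- small_dataset(seed = 13)
  graphs <- similarity_graphs(ds, lmi_params(kappa = 6, n_neighbors = 5))
  hn <- assemble_hetnet(graphs$W_l, ds$A, graphs$W_m)
  p <- lmi_params_demo(embed_dim = 6L, gae_epochs = 60L, gae_hidden = 24L,
                       walk_length = 15L, walks_per_node = 4L)
  embeddings <- embed_all(hn$H, params = p, seed = 1)
  for (E in embeddings) {
    expect_equal(dim(E), c(hn$r + hn$t, 6))
    expect_true(all(is.finite(E)))
  }
})

test_that("zero-degree nodes are rejected before any factorization", {
  H <- matrix(0, 4, 4); H[1, 2] <- H[2, 1] <- 1  # nodes 3,4 isolated
  expect_error(embed_le(H, dim = 1), "zero-degree")
  expect_error(embed_grarep(H, dim = 2), "zero-degree")
})

test_that("pair features concatenate the two node embeddings", {
  E <- rbind(c(1, 2), c(3, 4))  # one lncRNA, one miRNA, dim 2
  pf <- pair_features(E, tibble::tibble(i = 1, j = 1), r = 1)
  expect_equal(unname(pf[1, ]), c(1, 2, 3, 4))

  E2 <- matrix(rnorm(10 * 3), 10)
  pairs <- tidyr::expand_grid(i = 1:4, j = 1:6)
  pf2 <- pair_features(E2, pairs, r = 4)
  expect_equal(ncol(pf2), 6)  # 2 * dim for every pair
  # the lncRNA half only depends on i
  half <- pf2[, 1:3]
  for (ii in 1:4) {
    rows <- which(pairs$i == ii)
    expect_equal(half[rows, ], half[rep(rows[1], length(rows)), ],
                 ignore_attr = TRUE)
  }
  expect_error(pair_features(E2, tibble::tibble(i = 5, j = 1), r = 4),
               "out of range")
})
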