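test_that("k-mer spectra match direct enumeration on hand cases", {
  s1 <- tibble::tibble(id = "a", residues = "AAAAA")
  sp1 <- kmer_spectra(s1, k = 5)
  expect_equal(sum(sp1), 1)
  expect_equal(unname(sp1[1, "AAAAA"]), 1L)

  s2 <- tibble::tibble(id = "b", residues = "ACGUA")
  sp2 <- kmer_spectra(s2, k = 2)
  expect_equal(sum(sp2), 4)  # 5 - 2 + 1
  expect_equal(unname(sp2[1, c("AC", "CG", "GU", "UA")]), rep(1L, 4))
  expect_equal(sum(sp2[1, setdiff(colnames(sp2), c("AC", "CG", "GU", "UA"))]), 0)
})

test_that("5-spectrum of a random sequence equals a naive substring scan", {
  set.seed(7)
  seq300 <- paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE),
                  collapse = "")
  sp <- kmer_spectra(tibble::tibble(id = "x", residues = seq300), k = 5)
  oracle <- oracle_kmer_counts(seq300, 5)
  expect_identical(unname(sp[1, names(oracle)]), unname(oracle))
})

test_that("spectrum count conservation holds for generated sequences", {
  ds <- small_dataset(seed = 2)
  for (k in c(2L, 5L)) {
    sp <- kmer_spectra(ds$sequences, k = k)
    expect_equal(unname(rowSums(sp)),
                 nchar(ds$sequences$residues) - k + 1)
  }
})

test_that("sequences shorter than k are rejected by id", {
  seqs <- tibble::tibble(id = c("ok", "tiny"), residues = c("ACGUACG", "ACG"))
  expect_error(kmer_spectra(seqs, k = 5), "tiny")
})

test_that("two entities with one neighbor give the trivial similarity", {
  sp <- matrix(c(3, 1, 0, 2,
                 1, 3, 2, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  S <- lns_similarity(sp, kappa = 1)
  expect_equal(unname(S), matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("LNS rows are nonnegative and sum to one on fixture data", {
  ds <- small_dataset(seed = 4)
  sp <- kmer_spectra(dplyr::filter(ds$sequences, kind == "lncRNA"), k = 5)
  S <- lns_similarity(sp, kappa = 6)
  expect_true(all(S >= 0))
  expect_equal(unname(rowSums(S)), rep(1, nrow(S)), tolerance = 1e-8)
  expect_equal(unname(diag(S)), rep(0, nrow(S)))
})

test_that("LNS weights match a simplex grid-search oracle", {
  set.seed(11)
  # 4 entities with toy k=2 spectra in R^16, kappa = 2
  sp <- matrix(rpois(4 * 16, lambda = 3), nrow = 4,
               dimnames = list(paste0("e", 1:4), NULL))
  lambda <- 1e-6
  S <- lns_similarity(sp, kappa = 2, lambda = lambda)
  X <- sp / sqrt(rowSums(sp^2))
  for (i in 1:4) {
    nb <- which(S[i, ] > 0)
    expect_length(nb, 2)
    w_oracle <- oracle_simplex_weights(t(X[nb, ]), X[i, ], lambda)
    expect_equal(unname(S[i, nb]), w_oracle, tolerance = 2e-3)
  }
})

test_that("identical spectra fall back to uniform weights", {
  sp <- matrix(rep(c(2, 1, 0, 4), each = 5), nrow = 5,
               dimnames = list(paste0("e", 1:5), NULL))
  S <- lns_similarity(sp, kappa = 3)
  expect_equal(unname(S[1, S[1, ] > 0]), rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("top-k sparsification keeps row-wise maxima and symmetrizes", {
  S <- matrix(c(0, .7, .3,
                .2, 0, .8,
                .6, .4, 0), 3, byrow = TRUE)
  W <- topk_neighbor_graph(S, n_neighbors = 1)
  expect_equal(W, matrix(c(0, .7, .6,
                           .7, 0, .8,
                           .6, .8, 0), 3, byrow = TRUE))
  # keep-all case equals max(S, t(S)) with zero diagonal
  W2 <- topk_neighbor_graph(S, n_neighbors = 2)
  expect_equal(W2, pmax(S, t(S)) * (1 - diag(3)))
  expect_warning(topk_neighbor_graph(S, n_neighbors = 5), "keeping all")
  # ties break toward the lower column index
  St <- matrix(c(0, .5, .5, .2,
                 .5, 0, .1, .1,
                 .5, .1, 0, .1,
                 .2, .1, .1, 0), 4, byrow = TRUE)
  Wt <- topk_neighbor_graph(St, n_neighbors = 1, symmetrize = FALSE)
  expect_equal(unname(Wt[1, ]), c(0, .5, 0, 0))
})

test_that("zero-mutation blocks concentrate LNS mass within the block", {
  ds <- small_dataset(seed = 6, mutation_rate = 0)
  seqs <- dplyr::filter(ds$sequences, kind == "lncRNA")
  sp <- kmer_spectra(seqs, k = 5)
  S <- lns_similarity(sp, kappa = 6)
  for (i in seq_len(nrow(S))) {
    same <- seqs$block == seqs$block[i]
    expect_gte(sum(S[i, same]), sum(S[i, !same]))
  }
})
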