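test_that("base predictors emit probabilities and fit separable toys exactly", {
  r <- 6; t_ <- 6
  E <- rbind(matrix(1, 3, 4), matrix(-1, 3, 4),   # lncRNAs
             matrix(1, 3, 4), matrix(-1, 3, 4))   # miRNAs
  E <- E + matrix(rnorm(nrow(E) * 4, sd = 0.01), nrow(E))
  pairs <- tidyr::expand_grid(i = seq_len(r), j = seq_len(t_))
  pairs$label <- as.integer(pairs$i <= 3 & pairs$j <= 3)
  bp <- fit_base_predictor(E, r, pairs, num_trees = 100, seed = 1)
  sc <- predict(bp, pairs)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(as.integer(sc >= 0.5), pairs$label)  # training accuracy 1
  expect_error(fit_base_predictor(E, r, dplyr::mutate(pairs, label = 1L)),
               "both classes")
})

test_that("an oracle base score earns the largest stacking coefficient", {
  set.seed(31)
  n <- 400
  labels <- rbinom(n, 1, 0.3)
  oof <- cbind(ora = labels * 0.8 + 0.1,
               n1 = runif(n), n2 = runif(n), n3 = runif(n), n4 = runif(n))
  fit <- fit_stacking(oof, labels)
  co <- as.numeric(stats::coef(fit))[-1]
  expect_equal(which.max(abs(co)), 1)
})

test_that("identical base-score columns share their coefficients", {
  set.seed(32)
  n <- 300
  s <- runif(n)
  labels <- rbinom(n, 1, plogis(4 * s - 2))
  oof <- cbind(a = s, b = s, c = s)
  fit <- fit_stacking(oof, labels)
  co <- as.numeric(stats::coef(fit))[-1]
  # agreement is limited by the solver's convergence threshold
  expect_equal(co[1], co[2], tolerance = 1e-3)
  expect_equal(co[1], co[3], tolerance = 1e-3)
  expect_error(fit_stacking(cbind(c(NA, s[-1]), s), labels), "finite")
})

test_that("ensemble scores are monotone in a positively weighted base score", {
  set.seed(33)
  n <- 300
  s1 <- runif(n)
  labels <- rbinom(n, 1, plogis(6 * s1 - 3))
  oof <- cbind(s1 = s1, s2 = runif(n))
  fit <- fit_stacking(oof, labels)
  expect_gt(as.numeric(stats::coef(fit))[2], 0)
  grid <- cbind(s1 = seq(0, 1, 0.1), s2 = 0.5)
  pr <- as.numeric(predict(fit, newx = grid, type = "response"))
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the stacked ensemble trains only on training-fold pairs", {
  ds <- small_dataset(seed = 34)
  p <- lmi_params_demo(embed_dim = 6L, gae_epochs = 60L, gae_hidden = 24L,
                       walk_length = 15L, walks_per_node = 4L,
                       num_trees = 100L, fi_num_trees = 100L,
                       dann_epochs = 100L)
  graphs <- similarity_graphs(ds, p)
  folds <- make_folds(ds$A, n_folds = 3, seed = 2)
  test_pairs <- dplyr::filter(folds, fold == 1)
  train_pairs <- dplyr::filter(folds, fold != 1)
  res <- evaluate_split(ds$A, graphs, test_pairs, train_pairs, params = p,
                        models = c("grarep", "stack"), seed = 3,
                        return_scores = TRUE)
  # leakage audit: the embedded network contains no test-fold positive edge
  A_train <- attr(res, "A_train")
  expect_equal(sum(A_train[cbind(test_pairs$i, test_pairs$j)]), 0)
  # pair-set audit: training and test pairs are disjoint
  expect_equal(nrow(dplyr::inner_join(train_pairs, test_pairs,
                                      by = c("i", "j"))), 0)
  expect_true(all(c("grarep", "stack") %in% res$model))
})

test_that("evaluation is deterministic given the seed", {
  ds <- small_dataset(seed = 35)
  p <- lmi_params_demo(embed_dim = 6L, gae_epochs = 40L, gae_hidden = 16L,
                       walk_length = 12L, walks_per_node = 3L,
                       num_trees = 60L, fi_num_trees = 60L,
                       dann_epochs = 60L)
  r1 <- holdout_evaluate(ds, params = p, models = c("deepwalk", "gae"),
                         n_folds = 3, seed = 7)
  r2 <- holdout_evaluate(ds, params = p, models = c("deepwalk", "gae"),
                         n_folds = 3, seed = 7)
  expect_identical(r1, r2)
})

test_that("the attention ensemble scores pairs and reports tidy weights", {
  ds <- small_dataset(seed = 36)
  p <- lmi_params_demo(embed_dim = 6L, gae_epochs = 40L, gae_hidden = 16L,
                       walk_length = 12L, walks_per_node = 3L,
                       num_trees = 60L, fi_num_trees = 60L,
                       dann_epochs = 150L)
  res <- holdout_evaluate(ds, params = p, models = "attention",
                          n_folds = 3, seed = 8, return_scores = TRUE)
  sc <- attr(res, "scores")$attention
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(c("aupr", "auc", "f1", "acc", "rec", "spec", "pre") %in%
                    names(res)))
})

test_that("zero-ratio sparsity reproduces the standard run bit for bit", {
  ds <- small_dataset(seed = 37)
  p <- lmi_params_demo(embed_dim = 6L, gae_epochs = 40L, gae_hidden = 16L,
                       walk_length = 12L, walks_per_node = 3L,
                       num_trees = 60L, fi_num_trees = 60L, dann_epochs = 60L)
  sp <- sparsity_experiment(ds, ratios = 0, seeds = 5, params = p,
                            models = c("grarep", "le"), n_folds = 3)
  hd <- holdout_evaluate(ds, params = p, models = c("grarep", "le"),
                         n_folds = 3, seed = 5)
  expect_equal(dplyr::select(sp, -ratio, -seed), hd)
})
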