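#' Pipeline parameter set
#'
#' Collects every tunable parameter of the pipeline with the study defaults:
#' 5-spectrum similarity, top-10 neighbor graphs, 120-dimensional embeddings,
#' GraRep k-step 1, DeepWalk walk length 80 / 30 walks per node / window 30,
#' variational autoencoder with hidden width 512, stacking with
#' library-default forests, attention fusion of the GraRep and LE views with
#' a {240, 120} hidden stack and a 2000-tree forest. Override any field by
#' name; smaller settings are appropriate for small synthetic networks.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `lmi_params`.
#' @examples
#' lmi_params(embed_dim = 16, gae_hidden = 64)$embed_dim
#' @export
lmi_params <- function(...) {
  defaults <- list(
    k = 5L, kappa = 10L, lns_lambda = 1e-6, n_neighbors = 10L,
    embed_dim = 120L, grarep_k_step = 1L,
    walk_length = 80L, walks_per_node = 30L, window = 30L,
    dw_negative = 5L, dw_epochs = 5L, dw_lr = 0.025,
    gae_hidden = 512L, gae_variational = TRUE, gae_epochs = 200L,
    gae_lr = 0.01, hope_decay = NULL,
    dann_hidden = c(240L, 120L), dann_epochs = 200L, dann_lr = 0.01,
    proj_dim = NULL, fi_views = c("grarep", "le"),
    num_trees = 500L, fi_num_trees = 2000L, inner_folds = 5L,
    threshold = 0.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  structure(modifyList(defaults, over, keep.null = TRUE), class = "lmi_params")
}

#' Demo-scale parameter preset
#'
#' [lmi_params()] scaled to small networks (on the order of a hundred nodes,
#' as produced by [simulate_lmi_data()] defaults): the embedding dimension is
#' kept proportional to the node count (about 13%, matching the ratio of the
#' full-scale defaults), the walk corpus, autoencoder width and forest sizes
#' are reduced accordingly, and the attention network shrinks with the pair
#' feature width. Used by the package's own experiments on synthetic data.
#'
#' @param ... Named overrides applied on top of the preset.
#' @return A named list of class `lmi_params`.
#' @export
lmi_params_demo <- function(...) {
  preset <- lmi_params(
    embed_dim = 12L,
    walk_length = 40L, walks_per_node = 10L, window = 5L, dw_epochs = 3L,
    gae_hidden = 64L, gae_epochs = 200L,
    dann_hidden = c(48L, 24L), dann_epochs = 2000L, dann_lr = 0.1,
    num_trees = 300L, fi_num_trees = 2000L, inner_folds = 3L)
  do.call(lmi_params, modifyList(unclass(preset), list(...), keep.null = TRUE))
}

#' Stratified cross-validation folds over the pair grid
#'
#' Partitions all r*t lncRNA-miRNA pairs into `n_folds` folds,
#' stratified so that per-fold pair counts and per-fold positive counts each
#' differ by at most one. Cross-validation is over pairs (transductive link
#' prediction on a fixed node set). One fresh seeded shuffle per repeat.
#'
#' @param A Binary interaction matrix.
#' @param n_folds Number of folds (default 5).
#' @param repeats Number of repeated shuffles (the full study protocol uses
#'   20 repeats of 5-fold cross-validation).
#' @param seed Integer seed.
#' @return Tibble with `repeat_id`, `i`, `j`, `label`, `fold`.
#' @export
make_folds <- function(A, n_folds = 5L, repeats = 1L, seed = 1L) {
  assert_that(n_folds >= 2, "n_folds must be >= 2")
  assert_that(sum(A) >= n_folds, "fewer positives than folds")
  grid <- pair_grid(A)
  purrr::map_dfr(seq_len(repeats), function(rep_id) {
    with_seed(derive_seed(seed, rep_id), {
      f <- integer(nrow(grid))
      pos <- sample(which(grid$label == 1L))
      neg <- sample(which(grid$label == 0L))
      f[pos] <- rep_len(seq_len(n_folds), length(pos))
      offset <- length(pos) %% n_folds
      f[neg] <- ((seq_along(neg) - 1L + offset) %% n_folds) + 1L
      dplyr::mutate(grid, repeat_id = rep_id, fold = f, .before = 1)
    })
  })
}

#' Compute both similarity neighbor graphs of a dataset
#'
#' Runs the 5-spectrum / linear-neighborhood-similarity / top-k construction
#' for each entity kind. Uses sequences only, never interaction labels, so
#' the graphs can be computed once and reused across folds without leakage.
#'
#' @param dataset An `lmi_dataset`.
#' @param params An [lmi_params()] set.
#' @return List with `W_l` and `W_m`.
#' @export
similarity_graphs <- function(dataset, params = lmi_params()) {
  seqs <- dataset$sequences
  graph_for <- function(kind) {
    sp <- kmer_spectra(dplyr::filter(seqs, .data$kind == !!kind), k = params$k)
    S <- lns_similarity(sp, kappa = min(params$kappa, nrow(sp) - 1L),
                        lambda = params$lns_lambda)
    topk_neighbor_graph(S, n_neighbors = min(params$n_neighbors, nrow(S) - 1L))
  }
  list(W_l = graph_for("lncRNA"), W_m = graph_for("miRNA"))
}

embed_one <- function(H, method, params, seed) {
  E <- switch(method,
    le = embed_le(H, dim = params$embed_dim),
    grarep = embed_grarep(H, dim = params$embed_dim,
                          k_step = params$grarep_k_step),
    hope = embed_hope(H, dim = params$embed_dim,
                      katz_decay = params$hope_decay),
    deepwalk = embed_deepwalk(H, dim = params$embed_dim,
                              walk_length = params$walk_length,
                              walks_per_node = params$walks_per_node,
                              window = params$window,
                              negative = params$dw_negative,
                              epochs = params$dw_epochs,
                              learning_rate = params$dw_lr,
                              seed = derive_seed(seed, 21L)),
    gae = embed_gae(H, dim = params$embed_dim, hidden = params$gae_hidden,
                    variational = params$gae_variational,
                    epochs = params$gae_epochs,
                    learning_rate = params$gae_lr,
                    seed = derive_seed(seed, 22L)),
    stop("unknown embedding method: ", method))
  attr(E, "method") <- method
  E
}

#' Embed a heterogeneous network with several methods
#'
#' @param H Adjacency matrix or `hetnet` object.
#' @param methods Character vector of embedding methods.
#' @param params An [lmi_params()] set.
#' @param seed Integer seed for the stochastic methods.
#' @return Named list of embedding matrices.
#' @export
embed_all <- function(H, methods = c("le", "grarep", "hope", "deepwalk", "gae"),
                      params = lmi_params(), seed = 1L) {
  if (inherits(H, "hetnet")) H <- H$H
  setNames(lapply(methods, function(m) embed_one(H, m, params, seed)), methods)
}

BASE_METHODS <- c("le", "grarep", "hope", "deepwalk", "gae")

#' Evaluate models on one train/test split
#'
#' Core engine shared by [cross_validate()], [holdout_evaluate()] and
#' [sparsity_experiment()]. Test-fold positive edges are masked out of the
#' interaction block before the network is embedded, so embeddings never see
#' test labels; training pairs are all non-test pairs with labels from the
#' masked matrix.
#'
#' @param A Binary interaction matrix (current dataset state).
#' @param graphs List with `W_l`, `W_m` from [similarity_graphs()].
#' @param test_pairs Tibble with `i`, `j`, `label` for evaluation.
#' @param train_pairs Tibble with `i`, `j` (labels are re-read from the
#'   masked matrix).
#' @param params An [lmi_params()] set.
#' @param models Character subset of `"le"`, `"grarep"`, `"hope"`,
#'   `"deepwalk"`, `"gae"`, `"stack"` (prediction integration),
#'   `"attention"` (feature integration), `"no_attention"` (uniform-sum
#'   ablation).
#' @param seed Integer seed.
#' @param return_scores Also return per-model test scores.
#' @return Tibble of per-model metrics (plus a `scores` attribute when
#'   requested).
#' @export
evaluate_split <- function(A, graphs, test_pairs, train_pairs,
                           params = lmi_params(),
                           models = c(BASE_METHODS, "stack", "attention"),
                           seed = 1L, return_scores = FALSE) {
  A_train <- A
  A_train[cbind(test_pairs$i, test_pairs$j)] <- 0L
  hn <- assemble_hetnet(graphs$W_l, A_train, graphs$W_m)
  r <- hn$r

  train_pairs <- dplyr::mutate(train_pairs,
                               label = A_train[cbind(.data$i, .data$j)])

  need_embed <- unique(c(intersect(models, BASE_METHODS),
                         if (any(models %in% c("stack"))) BASE_METHODS,
                         if (any(models %in% c("attention", "no_attention")))
                           params$fi_views))
  embeddings <- embed_all(hn$H, need_embed, params, seed)

  scores <- list()
  base_needed <- if ("stack" %in% models) BASE_METHODS else
    intersect(models, BASE_METHODS)
  bases <- list()
  for (m in base_needed) {
    bases[[m]] <- fit_base_predictor(
      embeddings[[m]], r, train_pairs, num_trees = params$num_trees,
      seed = derive_seed(seed, 30L + match(m, BASE_METHODS)))
  }
  for (m in intersect(models, BASE_METHODS)) {
    scores[[m]] <- predict(bases[[m]], test_pairs)
  }
  if ("stack" %in% models) {
    st <- fit_stacked_ensemble(embeddings[BASE_METHODS], r, train_pairs,
                               inner_folds = params$inner_folds,
                               num_trees = params$num_trees,
                               seed = derive_seed(seed, 40L),
                               base_predictors = bases[BASE_METHODS])
    scores[["stack"]] <- predict(st, test_pairs)$score
  }
  for (m in intersect(models, c("attention", "no_attention"))) {
    fe <- fit_attention_ensemble(
      embeddings[params$fi_views], r, train_pairs,
      hidden = params$dann_hidden, proj_dim = params$proj_dim,
      attention = (m == "attention"), epochs = params$dann_epochs,
      learning_rate = params$dann_lr, num_trees = params$fi_num_trees,
      seed = derive_seed(seed, 50L))
    scores[[m]] <- predict(fe, test_pairs)$score
  }

  out <- purrr::map_dfr(names(scores), function(m) {
    dplyr::mutate(compute_metrics(scores[[m]], test_pairs$label,
                                  threshold = params$threshold),
                  model = m, .before = 1)
  })
  if (return_scores) {
    attr(out, "scores") <- scores
    attr(out, "A_train") <- A_train
  }
  out
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation over the pair grid: per fold, the
#' fold's positive edges are hidden from the heterogeneous network, all
#' models are retrained, and the fold's pairs are scored.
#'
#' @param dataset An `lmi_dataset`.
#' @param params An [lmi_params()] set.
#' @param models Models to evaluate (see [evaluate_split()]).
#' @param n_folds,repeats,seed Cross-validation controls.
#' @return Tibble with `repeat_id`, `fold`, `model` and the seven metrics.
#' @export
cross_validate <- function(dataset, params = lmi_params(),
                           models = c(BASE_METHODS, "stack", "attention"),
                           n_folds = 5L, repeats = 1L, seed = 1L) {
  graphs <- similarity_graphs(dataset, params)
  folds <- make_folds(dataset$A, n_folds = n_folds, repeats = repeats,
                      seed = derive_seed(seed, 3L))
  purrr::map_dfr(seq_len(repeats), function(rep_id) {
    fr <- dplyr::filter(folds, .data$repeat_id == rep_id)
    purrr::map_dfr(seq_len(n_folds), function(fd) {
      res <- evaluate_split(
        dataset$A, graphs,
        test_pairs = dplyr::filter(fr, .data$fold == fd),
        train_pairs = dplyr::filter(fr, .data$fold != fd),
        params = params, models = models,
        seed = derive_seed(seed, 1000L * rep_id + fd))
      dplyr::mutate(res, repeat_id = rep_id, fold = fd, .before = 1)
    })
  })
}

#' Single stratified holdout evaluation
#'
#' One fold of [cross_validate()]: hides the positives of one stratified
#' fold (a `1/n_folds` fraction of all pairs) and evaluates on that fold.
#' Cheaper than full cross-validation; used by the robustness experiments.
#'
#' @inheritParams cross_validate
#' @param return_scores Also return per-model test scores.
#' @return Tibble of per-model metrics on the held-out fold.
#' @export
holdout_evaluate <- function(dataset, params = lmi_params(),
                             models = c(BASE_METHODS, "stack", "attention"),
                             n_folds = 5L, seed = 1L, return_scores = FALSE) {
  graphs <- similarity_graphs(dataset, params)
  folds <- make_folds(dataset$A, n_folds = n_folds, repeats = 1L,
                      seed = derive_seed(seed, 3L))
  evaluate_split(dataset$A, graphs,
                 test_pairs = dplyr::filter(folds, .data$fold == 1L),
                 train_pairs = dplyr::filter(folds, .data$fold != 1L),
                 params = params, models = models,
                 seed = derive_seed(seed, 1001L),
                 return_scores = return_scores)
}

#' Network-sparsity robustness experiment
#'
#' For each removal ratio, randomly deletes that fraction of the known
#' interactions, rebuilds the heterogeneous network on the sparsified data
#' and re-evaluates every model (ratio grid 0.1-0.4 in the study protocol;
#' ratio 0 reproduces the standard run bit-for-bit under equal seeds).
#' Deleted links become unlabeled pairs. The similarity graphs depend only
#' on sequences and are computed once.
#'
#' @param dataset An `lmi_dataset`.
#' @param ratios Removal ratios in `[0, 1)`.
#' @param seeds Integer vector; the experiment is repeated per seed with the
#'   same seed paired across ratios.
#' @param params An [lmi_params()] set.
#' @param models Models to evaluate.
#' @param n_folds Holdout granularity passed to the evaluation.
#' @return Tibble with `ratio`, `seed`, `model` and the seven metrics.
#' @export
sparsity_experiment <- function(dataset, ratios = c(0, 0.1, 0.2, 0.3, 0.4),
                                seeds = 1:10, params = lmi_params(),
                                models = c(BASE_METHODS, "stack", "attention"),
                                n_folds = 5L) {
  assert_that(all(ratios >= 0 & ratios < 1), "ratios must lie in [0, 1)")
  graphs <- similarity_graphs(dataset, params)
  purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(ratios, function(ra) {
      A_cur <- if (ra > 0) {
        mask_interactions(dataset$A, ra, seed = derive_seed(sd, 77L))$A_masked
      } else dataset$A
      folds <- make_folds(A_cur, n_folds = n_folds, repeats = 1L,
                          seed = derive_seed(sd, 3L))
      res <- evaluate_split(A_cur, graphs,
                            test_pairs = dplyr::filter(folds, .data$fold == 1L),
                            train_pairs = dplyr::filter(folds, .data$fold != 1L),
                            params = params, models = models,
                            seed = derive_seed(sd, 1001L))
      dplyr::mutate(res, ratio = ra, seed = sd, .before = 1)
    })
  })
}

#' Plot a sparsity-experiment result
#'
#' Median AUPR per model across removal ratios.
#'
#' @param object Tibble from [sparsity_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sparsity <- function(object, ...) {
  med <- dplyr::summarise(dplyr::group_by(object, .data$ratio, .data$model),
                          aupr = median(.data$aupr), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$ratio, y = .data$aupr,
                                    colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of known interactions removed",
                  y = "median AUPR", colour = NULL) +
    ggplot2::theme_minimal()
}
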