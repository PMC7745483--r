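#' Fit a random-forest base predictor on one embedding
#'
#' Trains a probability random forest on the pair features of one embedding
#' method. One such predictor per embedding method forms the base layer of
#' the stacked ensemble.
#'
#' @param E `(r+t) x dim` embedding matrix.
#' @param r Number of lncRNAs.
#' @param train_pairs Tibble with `i`, `j`, `label`; must contain both
#'   classes.
#' @param num_trees Trees in the forest (library default 500).
#' @param seed Integer seed.
#' @return Object of class `lmi_base` with a `predict()` method returning
#'   scores in `[0, 1]`.
#' @export
fit_base_predictor <- function(E, r, train_pairs, num_trees = 500L, seed = 1L) {
  assert_that(length(unique(train_pairs$label)) == 2,
              "training pairs must contain both classes")
  F_ <- pair_features(E, train_pairs, r)
  fit <- ranger::ranger(
    x = F_, y = factor(train_pairs$label, levels = c(0, 1)),
    num.trees = num_trees, probability = TRUE,
    seed = derive_seed(seed, 0L), num.threads = 1L)
  structure(list(model = fit, E = E, r = r,
                 method = attr(E, "method") %||% "embedding"),
            class = "lmi_base")
}

#' @exportS3Method base::print
print.lmi_base <- function(x, ...) {
  cat(sprintf("<lmi_base> %s embedding, %d trees\n",
              x$method, x$model$num.trees))
  invisible(x)
}

#' @rdname fit_base_predictor
#' @param object An `lmi_base` predictor.
#' @param pairs Tibble with `i`, `j` columns to score.
#' @param ... Unused.
#' @export
predict.lmi_base <- function(object, pairs, ...) {
  F_ <- pair_features(object$E, pairs, object$r)
  as.numeric(predict(object$model, data = F_, num.threads = 1L)$predictions[, "1"])
}

#' Fit the logistic meta-learner on out-of-fold base scores
#'
#' Ridge-penalized (L2) logistic regression mapping the base predictors'
#' scores to an interaction probability. The penalty `lambda = 1/n` matches
#' the common default strength of an L2-regularized logistic regression.
#'
#' @param oof_scores `n x K` matrix of out-of-fold base-predictor scores.
#' @param labels 0/1 vector.
#' @return A fitted `glmnet` object with a single lambda.
#' @export
fit_stacking <- function(oof_scores, labels) {
  assert_that(all(is.finite(oof_scores)), "non-finite base scores")
  assert_that(length(unique(labels)) == 2, "labels must contain both classes")
  glmnet::glmnet(oof_scores, factor(labels, levels = c(0, 1)),
                 family = "binomial", alpha = 0,
                 lambda = 1 / nrow(oof_scores), standardize = FALSE,
                 thresh = 1e-12)
}

#' Fit the prediction-integration ensemble (stacked random forests)
#'
#' Trains one random-forest base predictor per embedding method and combines
#' their scores with an L2-regularized logistic regression meta-learner. The
#' meta-learner is fit on out-of-fold base scores produced by an inner
#' cross-validation inside the training fold (so it never sees in-sample,
#' overfit scores); the base predictors are then refit on the full training
#' fold for test-time scoring.
#'
#' @param embeddings Named list of embedding matrices (one per method).
#' @param r Number of lncRNAs.
#' @param train_pairs Tibble with `i`, `j`, `label`.
#' @param inner_folds Folds of the inner split generating out-of-fold scores.
#' @param num_trees Trees per base forest.
#' @param seed Integer seed.
#' @param base_predictors Optional named list of already-fitted [lmi_base]
#'   predictors (one per embedding, trained on `train_pairs`) to reuse as the
#'   test-time base layer instead of refitting.
#' @return Object of class `lmi_stack`.
#' @export
fit_stacked_ensemble <- function(embeddings, r, train_pairs, inner_folds = 5L,
                                 num_trees = 500L, seed = 1L,
                                 base_predictors = NULL) {
  assert_that(length(embeddings) >= 2, "need at least two base embeddings")
  assert_that(length(unique(train_pairs$label)) == 2,
              "training pairs must contain both classes")
  K <- length(embeddings)
  methods <- names(embeddings) %||% paste0("view", seq_len(K))
  n_tr <- nrow(train_pairs)

  fold <- with_seed(derive_seed(seed, 11L), {
    f <- integer(n_tr)
    for (lab in c(0L, 1L)) {
      idx <- sample(which(train_pairs$label == lab))
      f[idx] <- rep_len(seq_len(inner_folds), length(idx))
    }
    f
  })

  oof <- matrix(NA_real_, n_tr, K, dimnames = list(NULL, methods))
  for (k in seq_len(K)) {
    for (fd in seq_len(inner_folds)) {
      tr <- train_pairs[fold != fd, ]
      if (length(unique(tr$label)) < 2) next
      bp <- fit_base_predictor(embeddings[[k]], r, tr, num_trees = num_trees,
                               seed = derive_seed(seed, 100L * k + fd))
      oof[fold == fd, k] <- predict(bp, train_pairs[fold == fd, ])
    }
  }
  meta <- fit_stacking(oof, train_pairs$label)

  if (is.null(base_predictors)) {
    base <- lapply(seq_len(K), function(k) {
      fit_base_predictor(embeddings[[k]], r, train_pairs, num_trees = num_trees,
                         seed = derive_seed(seed, 1000L + k))
    })
    names(base) <- methods
  } else {
    assert_that(length(base_predictors) == K,
                "base_predictors must match the embeddings")
    base <- base_predictors
  }

  structure(list(base = base, meta = meta, methods = methods, r = r,
                 lambda = 1 / n_tr, n_train = n_tr),
            class = "lmi_stack")
}

#' @exportS3Method base::print
print.lmi_stack <- function(x, ...) {
  cat(sprintf("<lmi_stack> %d base predictors (%s), logistic meta-learner\n",
              length(x$base), paste(x$methods, collapse = ", ")))
  invisible(x)
}

#' Score pairs with a stacked ensemble
#'
#' @param object An `lmi_stack` model.
#' @param pairs Tibble with `i`, `j` columns.
#' @param ... Unused.
#' @return Tibble `i`, `j`, per-base-method score columns and the ensemble
#'   `score`.
#' @export
predict.lmi_stack <- function(object, pairs, ...) {
  base_scores <- vapply(object$base, function(bp) predict(bp, pairs),
                        numeric(nrow(pairs)))
  if (is.null(dim(base_scores))) base_scores <- matrix(base_scores, nrow = 1)
  score <- as.numeric(predict(object$meta, newx = base_scores, type = "response"))
  out <- tibble::as_tibble(as.data.frame(base_scores))
  dplyr::bind_cols(tibble::tibble(i = pairs$i, j = pairs$j), out,
                   tibble::tibble(score = score))
}

#' @export
tidy.lmi_stack <- function(x, ...) {
  co <- as.matrix(stats::coef(x$meta))
  tibble::tibble(term = rownames(co), estimate = as.numeric(co))
}

#' @export
glance.lmi_stack <- function(x, ...) {
  tibble::tibble(n_base = length(x$base), n_train = x$n_train,
                 lambda = x$lambda)
}
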