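#' Fit the feature-integration ensemble (attention fusion + random forest)
#'
#' Trains the deep attention network ([dann_train()]) on the training pairs
#' to learn per-view attention weights (and optional projections), extracts
#' the attention-merged pair features, and fits a random forest on them.
#' With `attention = FALSE` the merge is frozen at the unweighted sum of
#' views — the no-attention ablation.
#'
#' @param embeddings Named list of embedding views entering the fusion
#'   (the study setting uses the GraRep and LE views).
#' @param r Number of lncRNAs.
#' @param train_pairs Tibble with `i`, `j`, `label`; both classes required.
#' @param hidden DANN hidden layer widths.
#' @param proj_dim Optional per-view projection width (pair features get
#'   width `2 * proj_dim`).
#' @param attention Trainable softmax attention (`TRUE`) or unweighted-sum
#'   ablation (`FALSE`).
#' @param epochs,learning_rate DANN training controls.
#' @param num_trees Trees in the downstream forest (default 2000, the study
#'   setting).
#' @param seed Integer seed.
#' @return Object of class `lmi_attention`.
#' @export
fit_attention_ensemble <- function(embeddings, r, train_pairs,
                                   hidden = c(240L, 120L), proj_dim = NULL,
                                   attention = TRUE, epochs = 200L,
                                   learning_rate = 0.01, num_trees = 2000L,
                                   seed = 1L) {
  assert_that(length(unique(train_pairs$label)) == 2,
              "training pairs must contain both classes")
  params <- dann_train(embeddings, train_pairs, r, hidden = hidden,
                       proj_dim = proj_dim, attention = attention,
                       epochs = epochs, learning_rate = learning_rate,
                       seed = seed)
  F_ <- extract_pair_features(embeddings, params, train_pairs, r)
  rf <- ranger::ranger(
    x = F_, y = factor(train_pairs$label, levels = c(0, 1)),
    num.trees = num_trees, probability = TRUE,
    seed = derive_seed(seed, 7L), num.threads = 1L)
  structure(list(params = params, rf = rf, embeddings = embeddings, r = r,
                 methods = names(embeddings) %||%
                   paste0("view", seq_along(embeddings)),
                 attention = attention, n_train = nrow(train_pairs)),
            class = "lmi_attention")
}

#' @exportS3Method base::print
print.lmi_attention <- function(x, ...) {
  w <- attention_weights(x$params)
  cat(sprintf("<lmi_attention> views: %s; %s\n",
              paste(x$methods, collapse = ", "),
              if (x$attention) {
                paste0("attention weights (lncRNA): ",
                       paste(sprintf("%.3f", w$lncrna), collapse = ", "))
              } else "uniform (no-attention ablation)"))
  invisible(x)
}

#' Score pairs with a feature-integration ensemble
#'
#' @param object An `lmi_attention` model.
#' @param pairs Tibble with `i`, `j`.
#' @param ... Unused.
#' @return Tibble `i`, `j`, `score`.
#' @export
predict.lmi_attention <- function(object, pairs, ...) {
  F_ <- extract_pair_features(object$embeddings, object$params, pairs, object$r)
  score <- as.numeric(
    predict(object$rf, data = F_, num.threads = 1L)$predictions[, "1"])
  tibble::tibble(i = pairs$i, j = pairs$j, score = score)
}

#' @export
tidy.lmi_attention <- function(x, ...) {
  w <- attention_weights(x$params)
  tibble::tibble(
    view = rep(x$methods, 2),
    kind = rep(c("lncRNA", "miRNA"), each = x$params$K),
    weight = c(w$lncrna, w$mirna))
}

#' @export
glance.lmi_attention <- function(x, ...) {
  tr <- attr(x$params, "loss_trace")
  tibble::tibble(n_views = x$params$K, attention = x$attention,
                 n_train = x$n_train,
                 loss_initial = tr[1], loss_final = tr[length(tr)])
}

#' Plot attention weights per embedding view
#'
#' Bar chart of the trained softmax attention weights for the lncRNA side
#' and the miRNA side.
#'
#' @param object An `lmi_attention` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmi_attention <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$view, y = .data$weight,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "embedding view", y = "attention weight",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
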