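#' Read a pipeline configuration from YAML
#'
#' The configuration mirrors [lmi_params()] plus run controls:
#' `lncrna_fasta`, `mirna_fasta`, `interactions`, `outdir`, `models`,
#' `n_folds`, `repeats`, `seed`, `sparsity_ratios`, and a `params` block of
#' [lmi_params()] overrides.
#'
#' @param path YAML file path.
#' @return A list of class `lmi_config`.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' Build a pipeline configuration in code
#'
#' @param cfg Named list with the fields described in
#'   [read_pipeline_config()].
#' @return A validated `lmi_config`.
#' @export
as_pipeline_config <- function(cfg) {
  defaults <- list(models = c(BASE_METHODS, "stack", "attention"),
                   n_folds = 5L, repeats = 1L, seed = 1L,
                   sparsity_ratios = NULL, params = list())
  cfg <- modifyList(defaults, cfg, keep.null = TRUE)
  for (f in c("lncrna_fasta", "mirna_fasta", "interactions")) {
    assert_that(!is.null(cfg[[f]]), sprintf("config field `%s` is required", f))
    assert_that(file.exists(cfg[[f]]),
                sprintf("config path `%s` does not exist: %s", f, cfg[[f]]))
  }
  assert_that(!is.null(cfg$outdir), "config field `outdir` is required")
  cfg$params <- do.call(lmi_params, cfg$params)
  structure(cfg, class = "lmi_config")
}

#' Semantic hash of a configuration
#'
#' MD5 of the canonical YAML serialization (fields sorted); changes iff a
#' semantic field changes.
#'
#' @param cfg An `lmi_config` (or any list).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(canonical(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full prediction pipeline from a configuration
#'
#' Reads sequences and interactions, runs the similarity / network /
#' embedding / ensemble / evaluation chain by cross-validation, optionally
#' runs the sparsity experiment, fits the requested heads on the full data,
#' and writes every artifact (metrics TSV + JSON report, model bundle,
#' config copy) under `outdir` tagged with the config hash. Fully
#' reproducible given the seed.
#'
#' @param cfg An `lmi_config` from [read_pipeline_config()] or
#'   [as_pipeline_config()].
#' @return Invisibly, a list with `metrics`, `sparsity` (or `NULL`),
#'   `models` and `hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "lmi_config"))
  hash <- config_hash(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  lnc <- read_fasta(cfg$lncrna_fasta, kind = "lncRNA")
  mir <- read_fasta(cfg$mirna_fasta, kind = "miRNA")
  A <- read_interactions(cfg$interactions, lnc$id, mir$id)
  dataset <- structure(list(sequences = dplyr::bind_rows(lnc, mir), A = A,
                            edges = NULL, spec = NULL), class = "lmi_dataset")

  metrics <- cross_validate(dataset, params = cfg$params, models = cfg$models,
                            n_folds = cfg$n_folds, repeats = cfg$repeats,
                            seed = cfg$seed)
  utils::write.table(metrics, file.path(cfg$outdir, "cv_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sparsity <- NULL
  if (!is.null(cfg$sparsity_ratios)) {
    sparsity <- sparsity_experiment(dataset, ratios = cfg$sparsity_ratios,
                                    seeds = cfg$seed, params = cfg$params,
                                    models = cfg$models,
                                    n_folds = cfg$n_folds)
    utils::write.table(sparsity, file.path(cfg$outdir, "sparsity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # final models on the complete data, for downstream prediction
  graphs <- similarity_graphs(dataset, cfg$params)
  hn <- assemble_hetnet(graphs$W_l, A, graphs$W_m)
  embeddings <- embed_all(hn$H, BASE_METHODS, cfg$params, seed = cfg$seed)
  grid <- pair_grid(A)
  models <- list()
  if ("stack" %in% cfg$models) {
    models$stack <- fit_stacked_ensemble(embeddings, hn$r, grid,
                                         inner_folds = cfg$params$inner_folds,
                                         num_trees = cfg$params$num_trees,
                                         seed = cfg$seed)
  }
  if ("attention" %in% cfg$models) {
    models$attention <- fit_attention_ensemble(
      embeddings[cfg$params$fi_views], hn$r, grid,
      hidden = cfg$params$dann_hidden, proj_dim = cfg$params$proj_dim,
      epochs = cfg$params$dann_epochs,
      learning_rate = cfg$params$dann_lr,
      num_trees = cfg$params$fi_num_trees, seed = cfg$seed)
  }
  if (length(models)) {
    saveRDS(models, file.path(cfg$outdir, sprintf("models_%s.rds", hash)))
  }

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(metrics, .data$model),
    dplyr::across(c("aupr", "auc", "f1", "acc", "rec", "spec", "pre"),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop")
  report <- list(config_hash = hash, n_lncrna = nrow(A), n_mirna = ncol(A),
                 n_interactions = sum(A), summary = summary_tbl)
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "params")],
                   file.path(cfg$outdir, "config_used.yaml"))

  invisible(list(metrics = metrics, sparsity = sparsity, models = models,
                 hash = hash))
}
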