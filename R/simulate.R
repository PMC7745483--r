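#' Specification for a synthetic planted-block interaction dataset
#'
#' Describes a synthetic lncRNA/miRNA dataset with planted co-interacting
#' groups ("blocks"). Entities in a block are point-mutated copies of a shared
#' random ancestor sequence, so sequence similarity is informative for block
#' membership; interactions are drawn with a high within-block and a low
#' cross-block probability, so similarity is in turn informative for links.
#' This emulates, at reduced scale, the situation in curated interaction
#' databases where similar RNAs tend to share interaction partners.
#'
#' @param n_lncrna Number of lncRNA-like entities (r).
#' @param n_mirna Number of miRNA-like entities (t).
#' @param n_blocks Number of co-interacting groups; must not exceed either
#'   entity count.
#' @param lncrna_len_range Integer range for lncRNA-like sequence lengths
#'   (default 200-1000 nt, mirroring the >200 nt definition of lncRNAs).
#' @param mirna_len_range Integer range for miRNA-like sequence lengths
#'   (default 20-25 nt, the canonical mature miRNA length).
#' @param within_block_link_prob Probability of a link between a lncRNA and a
#'   miRNA in the same block.
#' @param cross_block_link_prob Probability of a link across blocks; must be
#'   strictly less than `within_block_link_prob`.
#' @param mutation_rate Per-base substitution probability applied to the block
#'   ancestor to derive each member sequence. Substitutions only, no indels.
#' @param seed Integer seed; the whole dataset is deterministic given the spec.
#'
#' @return An object of class `lmi_sim_spec`.
#' @examples
#' spec <- lmi_sim_spec(n_lncrna = 12, n_mirna = 6, n_blocks = 2, seed = 1)
#' @export
lmi_sim_spec <- function(n_lncrna = 60, n_mirna = 30, n_blocks = 3,
                         lncrna_len_range = c(200L, 1000L),
                         mirna_len_range = c(20L, 25L),
                         within_block_link_prob = 0.5,
                         cross_block_link_prob = 0.02,
                         mutation_rate = 0.05,
                         seed = 1L) {
  assert_that(n_lncrna >= 1 && n_mirna >= 1 && n_blocks >= 1,
              "entity and block counts must be positive")
  assert_that(n_lncrna >= n_blocks && n_mirna >= n_blocks,
              "each entity kind must have at least as many entities as blocks")
  assert_that(cross_block_link_prob >= 0 &&
                cross_block_link_prob < within_block_link_prob &&
                within_block_link_prob <= 1,
              "need 0 <= cross_block_link_prob < within_block_link_prob <= 1")
  assert_that(mutation_rate >= 0 && mutation_rate <= 1,
              "mutation_rate must be in [0, 1]")
  for (rg in list(lncrna_len_range, mirna_len_range)) {
    assert_that(length(rg) == 2 && rg[1] >= 1 && rg[1] <= rg[2],
                "length ranges must be increasing positive integer pairs")
  }
  structure(list(
    n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
    n_blocks = as.integer(n_blocks),
    lncrna_len_range = as.integer(lncrna_len_range),
    mirna_len_range = as.integer(mirna_len_range),
    within_block_link_prob = within_block_link_prob,
    cross_block_link_prob = cross_block_link_prob,
    mutation_rate = mutation_rate,
    seed = as.integer(seed)
  ), class = "lmi_sim_spec")
}

#' @exportS3Method base::print
print.lmi_sim_spec <- function(x, ...) {
  cat(sprintf(
    "<lmi_sim_spec> %d lncRNAs x %d miRNAs, %d blocks, P(link) %.3g within / %.3g cross, mutation %.3g, seed %d\n",
    x$n_lncrna, x$n_mirna, x$n_blocks, x$within_block_link_prob,
    x$cross_block_link_prob, x$mutation_rate, x$seed))
  invisible(x)
}

random_rna <- function(len) {
  paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
}

mutate_rna <- function(residues, rate) {
  if (rate == 0) return(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute with a uniformly chosen *different* base
    repl <- vapply(chars[hit], function(b) sample(setdiff(RNA_BASES, b), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

block_assignment <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

#' Generate synthetic lncRNA and miRNA sequences with planted blocks
#'
#' Each block gets an i.i.d. uniform random ancestor sequence per entity kind;
#' members of the block are independent point-mutated copies of that ancestor
#' (substitutions only). Intra-block k-mer-spectrum similarity therefore
#' exceeds inter-block similarity in expectation whenever the mutation rate is
#' moderate.
#'
#' @param spec An [lmi_sim_spec()].
#' @param k Spectrum word length the sequences must support; generation fails
#'   if the shortest admissible sequence would be shorter than `k`.
#' @return A tibble with columns `id`, `kind` (`"lncRNA"`/`"miRNA"`), `block`
#'   and `residues` (A/C/G/U string).
#' @export
generate_sequences <- function(spec, k = 5L) {
  stopifnot(inherits(spec, "lmi_sim_spec"))
  assert_that(spec$mirna_len_range[1] >= k && spec$lncrna_len_range[1] >= k,
              sprintf("sequence length lower bounds must be >= spectrum k = %d", k))
  with_seed(spec$seed, {
    make_kind <- function(n, n_blocks, len_range, kind, prefix) {
      blocks <- block_assignment(n, n_blocks)
      anc_len <- sample(seq(len_range[1], len_range[2]), n_blocks, replace = TRUE)
      ancestors <- vapply(anc_len, random_rna, "")
      residues <- vapply(seq_len(n), function(i) {
        mutate_rna(ancestors[blocks[i]], spec$mutation_rate)
      }, "")
      tibble::tibble(
        id = sprintf("%s%03d", prefix, seq_len(n)),
        kind = kind, block = blocks, residues = residues)
    }
    dplyr::bind_rows(
      make_kind(spec$n_lncrna, spec$n_blocks, spec$lncrna_len_range, "lncRNA", "lnc"),
      make_kind(spec$n_mirna, spec$n_blocks, spec$mirna_len_range, "miRNA", "mir"))
  })
}

#' Generate a planted-block bipartite interaction matrix
#'
#' `A[i, j] = 1` with the within-block probability when lncRNA `i` and miRNA
#' `j` share a block, otherwise with the cross-block probability; draws are
#' independent given the block assignment.
#'
#' @param spec An [lmi_sim_spec()].
#' @param lnc_blocks,mir_blocks Integer block labels for the lncRNAs and
#'   miRNAs (in entity order).
#' @return A binary `r` x `t` interaction matrix with entity ids as dimnames.
#' @export
generate_interactions <- function(spec, lnc_blocks, mir_blocks) {
  stopifnot(inherits(spec, "lmi_sim_spec"))
  assert_that(length(lnc_blocks) == spec$n_lncrna &&
                length(mir_blocks) == spec$n_mirna,
              "block assignments must cover both entity kinds")
  with_seed(derive_seed(spec$seed, 1L), {
    within <- outer(lnc_blocks, mir_blocks, `==`)
    p <- ifelse(within, spec$within_block_link_prob, spec$cross_block_link_prob)
    A <- matrix(rbinom(length(p), 1L, p), nrow = spec$n_lncrna)
    dimnames(A) <- list(sprintf("lnc%03d", seq_len(spec$n_lncrna)),
                        sprintf("mir%03d", seq_len(spec$n_mirna)))
    A
  })
}

#' Simulate a complete synthetic interaction dataset
#'
#' Convenience wrapper running [generate_sequences()] and
#' [generate_interactions()] under the spec's seed.
#'
#' @param spec An [lmi_sim_spec()].
#' @param k Spectrum word length passed to [generate_sequences()].
#' @return An object of class `lmi_dataset`: a list with `sequences` (tibble),
#'   `A` (binary interaction matrix), `edges` (tibble of known links) and
#'   `spec`.
#' @examples
#' ds <- simulate_lmi_data(lmi_sim_spec(n_lncrna = 12, n_mirna = 6,
#'                                      n_blocks = 2, seed = 7))
#' dim(ds$A)
#' @export
simulate_lmi_data <- function(spec, k = 5L) {
  sequences <- generate_sequences(spec, k = k)
  lnc <- dplyr::filter(sequences, .data$kind == "lncRNA")
  mir <- dplyr::filter(sequences, .data$kind == "miRNA")
  A <- generate_interactions(spec, lnc$block, mir$block)
  dimnames(A) <- list(lnc$id, mir$id)
  idx <- which(A == 1L, arr.ind = TRUE)
  edges <- tibble::tibble(lncrna_id = rownames(A)[idx[, 1]],
                          mirna_id = colnames(A)[idx[, 2]])
  edges <- dplyr::arrange(edges, .data$lncrna_id, .data$mirna_id)
  structure(list(sequences = sequences, A = A, edges = edges, spec = spec),
            class = "lmi_dataset")
}

#' @exportS3Method base::print
print.lmi_dataset <- function(x, ...) {
  cat(sprintf("<lmi_dataset> %d lncRNAs x %d miRNAs, %d known interactions (density %.3f)\n",
              nrow(x$A), ncol(x$A), sum(x$A), mean(x$A)))
  invisible(x)
}

#' Write a dataset to FASTA/TSV files with a JSON sidecar
#'
#' Writes one FASTA file per entity kind, the known interactions as a
#' two-column TSV edge list, and a JSON sidecar recording the generating spec
#' and the block assignment (so downstream oracles can recover the planted
#' structure).
#'
#' @param dataset An `lmi_dataset`.
#' @param dir Output directory, created if missing.
#' @return The directory, invisibly.
#' @export
write_lmi_data <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lmi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- dataset$sequences
  write_fasta(dplyr::filter(seqs, .data$kind == "lncRNA"),
              file.path(dir, "lncrna.fasta"))
  write_fasta(dplyr::filter(seqs, .data$kind == "miRNA"),
              file.path(dir, "mirna.fasta"))
  utils::write.table(dataset$edges, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(spec = unclass(dataset$spec),
                  blocks = list(lncrna = seqs$block[seqs$kind == "lncRNA"],
                                mirna = seqs$block[seqs$kind == "miRNA"]))
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset previously written by [write_lmi_data()]
#'
#' @param dir Directory containing `lncrna.fasta`, `mirna.fasta` and
#'   `interactions.tsv`.
#' @return An `lmi_dataset` (without the generating spec unless the JSON
#'   sidecar is present).
#' @export
read_lmi_data <- function(dir) {
  lnc <- read_fasta(file.path(dir, "lncrna.fasta"), kind = "lncRNA")
  mir <- read_fasta(file.path(dir, "mirna.fasta"), kind = "miRNA")
  A <- read_interactions(file.path(dir, "interactions.tsv"), lnc$id, mir$id)
  sequences <- dplyr::bind_rows(lnc, mir)
  side <- file.path(dir, "dataset.json")
  spec <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    sequences$block <- c(meta$blocks$lncrna, meta$blocks$mirna)
    spec <- do.call(lmi_sim_spec, meta$spec[setdiff(names(meta$spec), NULL)])
  }
  idx <- which(A == 1L, arr.ind = TRUE)
  edges <- tibble::tibble(lncrna_id = rownames(A)[idx[, 1]],
                          mirna_id = colnames(A)[idx[, 2]])
  structure(list(sequences = sequences, A = A,
                 edges = dplyr::arrange(edges, .data$lncrna_id, .data$mirna_id),
                 spec = spec),
            class = "lmi_dataset")
}
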