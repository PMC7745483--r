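#' Read RNA sequences from a FASTA file
#'
#' Reads a FASTA file, takes the id from the header up to the first
#' whitespace, upper-cases the residues and normalizes DNA `T` to RNA `U`
#' (both entity kinds are handled on a single A/C/G/U alphabet internally).
#'
#' @param path FASTA file path.
#' @param kind Entity kind label attached to every record
#'   (`"lncRNA"` or `"miRNA"`).
#' @return A tibble with columns `id`, `kind`, `residues`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some description", "acgt"), tf)
#' read_fasta(tf, kind = "miRNA")
#' @export
read_fasta <- function(path, kind = c("lncRNA", "miRNA")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), kind = character(),
                          residues = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  residues <- chartr("T", "U", toupper(unname(as.character(set))))
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0,
              paste0("duplicate sequence ids: ", paste(dup, collapse = ", ")))
  empty <- ids[nchar(residues) == 0]
  assert_that(length(empty) == 0,
              paste0("empty sequences for ids: ", paste(empty, collapse = ", ")))
  bad <- ids[grepl("[^ACGU]", residues)]
  assert_that(length(bad) == 0,
              paste0("unsupported residues (need A/C/G/T/U) in: ",
                     paste(bad, collapse = ", ")))
  tibble::tibble(id = ids, kind = kind, residues = residues)
}

#' Write sequence records to FASTA
#'
#' @param sequences Tibble with `id` and `residues` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences$residues, sequences$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a two-column interaction edge list into a binary matrix
#'
#' Reads a TSV of `lncrna_id<TAB>mirna_id` rows, collapses duplicated rows
#' (count reported via `message()`), rejects edges referencing unknown ids
#' (reported and attached as the `"rejected"` attribute) and returns the
#' binary interaction matrix ordered by the supplied id vectors.
#'
#' @param path TSV edge list path (a header line `lncrna_id  mirna_id` is
#'   detected and skipped).
#' @param lncrna_ids,mirna_ids Ordered entity ids defining the matrix layout.
#' @return Binary `r` x `t` matrix with `dimnames = list(lncrna_ids, mirna_ids)`
#'   and attributes `n_duplicates` and `rejected` (tibble).
#' @export
read_interactions <- function(path, lncrna_ids, mirna_ids) {
  assert_that(file.exists(path), sprintf("edge list not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("lncrna_id", "mirna_id"),
                          colClasses = "character")
  if (nrow(df) > 0 && identical(tolower(df[1, 1]), "lncrna_id")) {
    df <- df[-1, , drop = FALSE]
  }
  n_dup <- sum(duplicated(df))
  if (n_dup > 0) message(n_dup, " duplicated interaction(s) collapsed")
  df <- unique(df)
  known <- df$lncrna_id %in% lncrna_ids & df$mirna_id %in% mirna_ids
  rejected <- tibble::as_tibble(df[!known, , drop = FALSE])
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " edge(s) reference unknown ids and were rejected")
  }
  df <- df[known, , drop = FALSE]
  assert_that(nrow(df) > 0, "no surviving interaction edges after validation")
  A <- matrix(0L, length(lncrna_ids), length(mirna_ids),
              dimnames = list(lncrna_ids, mirna_ids))
  A[cbind(match(df$lncrna_id, lncrna_ids), match(df$mirna_id, mirna_ids))] <- 1L
  attr(A, "n_duplicates") <- n_dup
  attr(A, "rejected") <- rejected
  A
}
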