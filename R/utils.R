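# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop unless a condition holds
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Check that a matrix is square, symmetric, nonnegative and finite
#' @noRd
check_adjacency <- function(H, name = "H", tol = 1e-8) {
  assert_that(is.matrix(H) && nrow(H) == ncol(H),
              sprintf("`%s` must be a square matrix", name))
  assert_that(all(is.finite(H)), sprintf("`%s` contains non-finite entries", name))
  assert_that(all(H >= 0), sprintf("`%s` must be nonnegative", name))
  assert_that(max(abs(H - t(H))) <= tol, sprintf("`%s` must be symmetric", name))
  invisible(TRUE)
}

#' Number of connected components of a nonnegative adjacency matrix
#' @noRd
n_components <- function(H) {
  n <- nrow(H)
  adj <- H > 0
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  comps
}

#' Derive a component seed from a pipeline seed by a fixed offset
#'
#' All randomness in the package flows from one pipeline seed; each stochastic
#' component draws its own seed at a fixed offset so that stages can be rerun
#' in isolation. Kept below 2^31 by wrapping.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Run code with a locally-set RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # log(1 + exp(x)) without overflow and without ifelse()'s overhead
  pos <- x > 0
  x * pos + log1p(exp(x - 2 * x * pos))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
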