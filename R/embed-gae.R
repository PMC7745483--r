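#' (Variational) graph autoencoder embedding
#'
#' Two-layer graph-convolutional encoder with identity node features and an
#' inner-product decoder, trained full-batch by Adam to reconstruct the
#' adjacency. The reconstruction loss is the class-weighted binary
#' cross-entropy over the full node grid (positive entries upweighted by the
#' negative/positive ratio, the usual correction for sparse graphs); the
#' variational mode adds the Gaussian reparameterization and a KL term and is
#' the default. Returns the latent mean matrix.
#'
#' @param H Symmetric nonnegative adjacency matrix.
#' @param dim Latent dimension.
#' @param hidden Hidden layer width (default 512, the study setting).
#' @param variational Use the variational autoencoder (default `TRUE`).
#' @param epochs Training epochs (full batch).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed for the initialization and reparameterization
#'   noise.
#' @return `n x dim` matrix with attributes `loss_initial`/`loss_final`
#'   (total objective) and `recon_initial`/`recon_final` (reconstruction
#'   term only).
#' @export
embed_gae <- function(H, dim = 120L, hidden = 512L, variational = TRUE,
                      epochs = 200L, learning_rate = 0.01, seed = 1L) {
  if (inherits(H, "hetnet")) H <- H$H
  check_adjacency(H)
  n <- nrow(H)

  # symmetric-normalized adjacency with self-loops; binary reconstruction target
  A_tilde <- H + diag(n)
  dh <- 1 / sqrt(rowSums(A_tilde))
  An <- (dh * A_tilde) * rep(dh, each = n)
  target <- (H > 0) + 0
  diag(target) <- 1
  n_pos <- sum(target)
  pos_weight <- (n * n - n_pos) / n_pos
  norm <- n * n / (2 * (n * n - n_pos))

  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }

  with_seed(derive_seed(seed, 0L), {
    W0 <- glorot(n, hidden)
    W1 <- glorot(hidden, dim)
    W2 <- if (variational) glorot(hidden, dim) else NULL

    adam <- function() list(m = 0, v = 0)
    st <- list(W0 = adam(), W1 = adam(), W2 = adam())
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- function(W, g, s, t) {
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mhat <- s$m / (1 - b1^t); vhat <- s$v / (1 - b2^t)
      list(W = W - learning_rate * mhat / (sqrt(vhat) + eps), s = s)
    }

    loss_initial <- NA_real_
    recon_initial <- NA_real_
    loss <- NA_real_
    recon <- NA_real_
    for (t in seq_len(epochs)) {
      A1 <- An %*% W0
      H1 <- pmax(A1, 0)
      AH1 <- An %*% H1
      Mu <- AH1 %*% W1
      if (variational) {
        Lsig <- AH1 %*% W2
        Lsig <- pmin(Lsig, 10)  # keeps exp() finite
        noise <- matrix(rnorm(n * dim), n, dim)
        Z <- Mu + noise * exp(Lsig)
      } else {
        Z <- Mu
      }
      S <- tcrossprod(Z)
      # weighted BCE with logits
      recon <- norm * mean(pos_weight * target * softplus(-S) +
                             (1 - target) * softplus(S))
      loss <- recon
      if (variational) {
        loss <- loss - 0.5 / n * sum(1 + 2 * Lsig - Mu^2 - exp(2 * Lsig))
      }
      if (!is.finite(loss)) {
        stop(sprintf("GAE training diverged at epoch %d (loss not finite)", t),
             call. = FALSE)
      }
      if (t == 1) { loss_initial <- loss; recon_initial <- recon }

      sig <- sigmoid(S)
      dS <- norm / (n * n) * (sig * (1 + (pos_weight - 1) * target) - pos_weight * target)
      dZ <- (dS + t(dS)) %*% Z
      dMu <- dZ
      if (variational) {
        dMu <- dMu + Mu / n
        dLsig <- dZ * noise * exp(Lsig) + (exp(2 * Lsig) - 1) / n
        dLsig[Lsig >= 10] <- 0
        dW2 <- crossprod(H1, An %*% dLsig)
      }
      dW1 <- crossprod(H1, An %*% dMu)
      dH1 <- (An %*% dMu) %*% t(W1)
      if (variational) dH1 <- dH1 + (An %*% dLsig) %*% t(W2)
      dA1 <- dH1 * (A1 > 0)
      dW0 <- crossprod(An, dA1)

      u <- step(W0, dW0, st$W0, t); W0 <- u$W; st$W0 <- u$s
      u <- step(W1, dW1, st$W1, t); W1 <- u$W; st$W1 <- u$s
      if (variational) { u <- step(W2, dW2, st$W2, t); W2 <- u$W; st$W2 <- u$s }
    }

    A1 <- An %*% W0
    H1 <- pmax(A1, 0)
    E <- (An %*% H1) %*% W1  # latent mean
    rownames(E) <- rownames(H)
    attr(E, "loss_initial") <- loss_initial
    attr(E, "loss_final") <- loss
    attr(E, "recon_initial") <- recon_initial
    attr(E, "recon_final") <- recon
    E
  })
}
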