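#' Two-dimensional t-SNE embedding
#'
#' t-distributed stochastic neighbor embedding of a feature matrix (for
#' example the hidden-state embedding of [hidden_embedding()]): Gaussian
#' input affinities calibrated per point to the target perplexity by binary
#' search, Student-t output affinities, and momentum gradient descent on the
#' Kullback-Leibler divergence with early exaggeration. Deterministic under
#' a fixed seed.
#'
#' @param x A numeric matrix, one row per observation (`n >= 3 * perplexity`).
#' @param perplexity Target perplexity. Default 10.
#' @param seed Integer seed for the random initialization.
#' @param n_iter Gradient iterations. Default 500.
#' @param learning_rate Step size. Default 100.
#' @return An `n x 2` matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 10, seed = 1L, n_iter = 500,
                       learning_rate = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3 * perplexity) abort("need at least 3 * perplexity observations.")
  sq <- rowSums(x^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  if (max(D2) == 0) abort("degenerate input: all rows are identical.")

  # Per-point precision calibrated to the target entropy log(perplexity).
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(60)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        hi <- beta; beta <- beta / 2; next
      }
      p <- w / sw
      Hb <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(Hb - target) < 1e-5) break
      if (Hb > target) {         # too flat: increase precision
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- exp(-di * beta) / sum(exp(-di * beta))
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  exag_iters <- max(20L, round(n_iter / 5))
  switch_iter <- max(50L, round(n_iter / 2))
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(n_iter)) {
      Pe <- if (iter <= exag_iters) P * 12 else P
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      Lm <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(Lm)) - Lm) %*% Y
      momentum <- if (iter <= switch_iter) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- momentum * inc - learning_rate * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
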