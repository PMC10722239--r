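# Exact t-SNE on a precomputed distance matrix (van der Maaten & Hinton's
# original O(n^2) formulation). Population sizes here are a few hundred at
# most, so the exact gradient is both affordable and bit-reproducible for a
# fixed seed.

# Conditional input probabilities via per-point binary search on the
# Gaussian precision to hit the target perplexity.
.tsne_input_p <- function(D2, perplexity, tol = 1e-5, max_tries = 64L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (k in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne_embed <- function(D, perplexity, seed, max_iter = 1000L, eta = 200,
                        exaggeration = 12, exag_iter = 250L) {
  n <- nrow(D)
  P <- .tsne_input_p(D^2, perplexity)
  Y <- with_seed(seed, matrix(rnorm(n * 2L, sd = 1e-4), n, 2L))
  G <- matrix(0, n, 2L)      # update (momentum) term
  gains <- matrix(1, n, 2L)
  momentum <- 0.5
  Pe <- P * exaggeration
  for (it in seq_len(max_iter)) {
    if (it == exag_iter + 1L) Pe <- P
    if (it == 251L) momentum <- 0.8
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2,
                               gains * 0.8))
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
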