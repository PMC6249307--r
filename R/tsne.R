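# Exact (O(n^2)) t-SNE. Phantom sections have at most a few thousand tissue
# pixels, so the exact algorithm is both feasible and reproducible; no
# approximate tree-based variant is needed at this scale.

# Binary search per point for the Gaussian precision that hits the target
# perplexity; returns the row-normalized conditional probabilities.
tsne_conditional_p <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP <= 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P
}

#' Exact t-SNE embedding
#'
#' Standard t-SNE with early exaggeration, momentum and adaptive gains,
#' computed with exact pairwise affinities. Deterministic for a fixed seed.
#'
#' @param X numeric matrix (observations x variables).
#' @param dims embedding dimensionality (3 for the Lab color embedding).
#' @param perplexity target perplexity; reduced automatically (with a
#'   warning) if it exceeds `(n - 1) / 3`.
#' @param max_iter gradient-descent iterations.
#' @param seed integer seed for the initialization.
#' @param eta learning rate.
#' @return n x `dims` matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, dims = 3, perplexity = 30, max_iter = 500,
                       seed = 1L, eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n >= 4, "t-SNE needs at least 4 observations")
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %.1f too large for n = %d; using %.1f",
                    perplexity, n, max_perp), call. = FALSE)
    perplexity <- max_perp
  }

  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)

  P <- tsne_conditional_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    dY <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    exag <- 12
    P_run <- P * exag
    for (iter in seq_len(max_iter)) {
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (P_run - Q) * num
      grad <- 4 * (rowSums(L) * Y - L %*% Y)

      momentum <- if (iter < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
      if (iter == 100) P_run <- P
    }
    Y
  })
}
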