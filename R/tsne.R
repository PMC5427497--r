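# Exact (O(n^2)) t-SNE with perplexity calibration, early exaggeration
# and momentum gradient descent -- adequate at the ~1000-point scale used
# for layer-activation visualization.

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  diag(D2) <- 0
  D2[D2 < 0] <- 0
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 10; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional stochastic neighbour embedding
#'
#' Embeds a feature matrix into 2-D with exact t-SNE (Gaussian input
#' affinities calibrated to `perplexity`, Student-t output kernel, early
#' exaggeration, momentum gradient descent).  Deterministic under a fixed
#' seed.
#'
#' @param X Numeric feature matrix (n rows >= 3) without constant overall
#'   value.
#' @param seed Integer seed for the initial layout.
#' @param perplexity Effective neighbourhood size.
#' @param n_iter Gradient-descent iterations.
#' @param max_points If `X` has more rows, a random subsample of this
#'   size is embedded (ids kept in rownames); mirrors the usual practice
#'   of embedding ~1000 random cells.
#' @return n x 2 matrix of coordinates with attributes `seed`,
#'   `perplexity`, `sampled_rows`.
#' @export
embed_2d <- function(X, seed = 1L, perplexity = 30, n_iter = 400,
                     max_points = 1000) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 points")
  if (max(abs(X - mean(X))) < 1e-12)
    stop("constant feature matrix cannot be embedded")
  sampled <- seq_len(nrow(X))
  if (nrow(X) > max_points)
    sampled <- with_seed(derive_seed(seed, 1L),
                         sort(sample.int(nrow(X), max_points)))
  Xs <- X[sampled, , drop = FALSE]
  n <- nrow(Xs)
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- tsne_affinities(Xs, perplexity)
  with_seed(derive_seed(seed, 2L), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(n_iter)) {
      ex <- if (iter <= 100) 4 else 1
      sq <- rowSums(Y^2)
      W <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(W) <- 0
      Q <- pmax(W / sum(W), 1e-12)
      L <- (ex * P - Q) * W
      G <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (iter <= 250) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(G) != sign(dY), gains + 0.2,
                                 gains * 0.8))
      dY <- mom * dY - 200 * gains * G
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(Xs)
    structure(Y, seed = seed, perplexity = perplexity,
              sampled_rows = sampled)
  })
}
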