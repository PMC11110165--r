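# Exact t-distributed stochastic neighbor embedding.
#
# The campaigns visualize at most a few hundred points, so the exact O(n^2)
# formulation is used: Gaussian input affinities with a per-point bandwidth
# found by binary search on the perplexity, Student-t output affinities,
# gradient descent with momentum and early exaggeration. Only seeded
# reproducibility is claimed - t-SNE coordinates have no intrinsic scale.

# Conditional affinities for one point: binary search for the precision
# giving the requested entropy.
tsne_p_row <- function(d2_row, perplexity) {
  target <- log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (iter in 1:64) {
    p <- exp(-d2_row * beta)
    sp <- sum(p)
    if (sp == 0) { H <- 0; pn <- p }
    else {
      pn <- p / sp
      H <- log(sp) + beta * sum(d2_row * p) / sp
    }
    dH <- H - target
    if (abs(dH) < 1e-6) break
    if (dH > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  pn
}

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- d2[i, -i]
    P[i, -i] <- tsne_p_row(row, perplexity)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Core gradient-descent loop.
tsne_embed <- function(X, perplexity, seed, max_iter = 600) {
  n <- nrow(X)
  P <- tsne_affinities(X, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)  # momentum buffer
  gains <- matrix(1, n, 2)
  eta <- 100
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 12 else 1
    d2y <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + d2y); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    M <- (ex * P - Q) * W
    grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed candidate points into two dimensions with t-SNE
#'
#' Points are one-hot / standardized encoded, the columns of the excluded
#' parameters are dropped (by default the substrate, so that the map shows
#' reaction *conditions*), and the exact t-SNE objective is minimized.
#' Deterministic for a fixed seed.
#'
#' @param points data frame of candidate points.
#' @param space the parameter space.
#' @param exclude parameter names excluded from the dissimilarity.
#' @param perplexity effective neighbor count; must be below the number of
#'   points (10 suits the ~50-observation campaign maps).
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return an object of class `rxn_embedding`: data frame `coords` (columns
#'   `x`, `y`), plus the excluded fields, perplexity, seed and encoding.
#' @export
embed_points <- function(points, space, exclude = "alkyne", perplexity = 10,
                         seed = 1, max_iter = 600) {
  n <- nrow(points)
  if (n < 5) stop_rxnbo("need at least 5 points to embed", "rxnbo_config_error")
  if (perplexity >= n)
    stop_rxnbo("perplexity must be below the number of points", "rxnbo_config_error")
  encoding <- build_encoding(space)
  X <- encode_points(points, encoding)
  drop_cols <- unlist(lapply(encoding$blocks[names(encoding$blocks) %in% exclude],
                             `[[`, "cols"))
  if (length(drop_cols)) X <- X[, -drop_cols, drop = FALSE]
  Y <- tsne_embed(X, perplexity, seed, max_iter)
  if (!all(is.finite(Y))) stop_rxnbo("t-SNE diverged to non-finite coordinates",
                                     "rxnbo_fit_error")
  structure(list(coords = data.frame(x = Y[, 1], y = Y[, 2]),
                 points = points, exclude = exclude, perplexity = perplexity,
                 seed = seed, encoding = encoding),
            class = "rxn_embedding")
}
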