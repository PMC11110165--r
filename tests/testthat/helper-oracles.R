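# Independent oracles used to cross-check the implementation paths. These
# deliberately use naive loops and solve() so they share no code with the
# package internals they verify.

# Matern-5/2 kernel between two encoded vectors, scalar arithmetic only.
bf_kernel <- function(xi, xj, blocks, lengthscales, signal_sd) {
  r2 <- 0
  for (b in seq_along(blocks)) {
    cols <- blocks[[b]]$cols
    d2 <- sum((xi[cols] - xj[cols])^2)
    r2 <- r2 + d2 / lengthscales[b]^2
  }
  r <- sqrt(r2)
  signal_sd^2 * (1 + sqrt(5) * r + 5 * r2 / 3) * exp(-sqrt(5) * r)
}

# Textbook Gaussian conditioning with an explicit inverse: mean and sd of the
# latent function at each row of Xs given training (X, y) and the model's
# hyperparameters.
bf_gp_predict <- function(model, Xs) {
  X <- model$X
  y <- model$y_raw - model$ymean
  n <- nrow(X)
  blocks <- model$encoding$blocks
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- bf_kernel(X[i, ], X[j, ], blocks, model$lengthscales, model$signal_sd)
  K <- K + diag(model$noise_sd^2, n)
  Kinv <- solve(K)
  m <- nrow(Xs)
  mu <- numeric(m); sd <- numeric(m)
  for (s in seq_len(m)) {
    ks <- numeric(n)
    for (i in seq_len(n))
      ks[i] <- bf_kernel(X[i, ], Xs[s, ], blocks, model$lengthscales, model$signal_sd)
    mu[s] <- model$ymean + sum(ks * (Kinv %*% y))
    v <- model$signal_sd^2 - drop(t(ks) %*% Kinv %*% ks)
    sd[s] <- sqrt(max(v, 0))
  }
  data.frame(mean = mu, sd = sd)
}

# Brute-force convergence scan: explicit double loop over alkynes and
# observation indices.
bf_replay <- function(observations, threshold = 0.8) {
  alks <- unique(as.character(observations$alkyne))
  first <- stats::setNames(rep(NA_integer_, length(alks)), alks)
  n_before <- stats::setNames(rep(0L, length(alks)), alks)
  for (a in alks) {
    for (i in seq_len(nrow(observations))) {
      if (observations$alkyne[i] == a) {
        if (observations$conversion[i] > threshold) { first[a] <- i; break }
        n_before[a] <- n_before[a] + 1L
      }
    }
  }
  list(first = first, n_before = n_before)
}

# A small mixed space for design/campaign tests: one polar solvent, three
# poor ones, coarse levels. 792 feasible points.
toy_campaign_space <- function() {
  list(
    param_def("alkyne", "categorical",
              c("2-ethynyltoluene", "4-ethynyltoluene",
                "1-chloro-2-ethynylbenzene", "1-chloro-4-ethynylbenzene")),
    param_def("chloramine_eq", "ordinal-numeric", c(0, 1, 2)),
    param_def("solvent", "categorical", c("MeOH", "THF", "DMF", "DCM")),
    param_def("iodine_source", "categorical", c("KI", "NaI", "TBAI", "NH4I", "NIS")),
    param_def("iodine_source_eq", "ordinal-numeric", c(0, 1, 2)),
    param_def("catalyst", "categorical", c("PTSA", "AcOH", "none")),
    param_def("catalyst_eq", "ordinal-numeric", c(0, 1)),
    param_def("temperature", "ordinal-numeric", c(25, 45, 65))
  )
}

toy_campaign_grid <- function() {
  build_grid(toy_campaign_space(), default_constraints())
}

# A minimal fully-crossed two-parameter space.
tiny_space <- function() {
  list(param_def("solvent", "categorical", c("DCM", "DMF")),
       param_def("temperature", "ordinal-numeric", c(25, 95)))
}
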