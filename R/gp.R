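# Gaussian-process surrogate over the encoded grid.
#
# A single GP models the merit of all substrates jointly (the substrate
# one-hot block is part of the features), which is how information gained on
# one alkyne transfers to the others. Kernel: Matern-5/2 on the one-hot /
# standardized encoding with one length-scale per parameter block (automatic
# relevance per block), fitted signal variance and observation-noise
# variance. Hyperparameters maximize the log marginal likelihood from a
# seeded multi-start so refits are reproducible.

# Per-block squared distances between the rows of Xa and Xb.
block_sqdist <- function(Xa, Xb, encoding) {
  lapply(encoding$blocks, function(b) {
    A <- Xa[, b$cols, drop = FALSE]
    B <- Xb[, b$cols, drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    pmax(d2, 0)
  })
}

# Matern-5/2 kernel from per-block squared distances and per-block
# length-scales.
matern52 <- function(d2_blocks, lengthscales, signal_sd) {
  r2 <- 0
  for (i in seq_along(d2_blocks)) r2 <- r2 + d2_blocks[[i]] / lengthscales[i]^2
  r <- sqrt(r2)
  s5r <- sqrt(5) * r
  signal_sd^2 * (1 + s5r + (5 / 3) * r2) * exp(-s5r)
}

gp_nll <- function(theta, d2, y, n_blocks) {
  ls <- exp(theta[seq_len(n_blocks)])
  sf <- exp(theta[n_blocks + 1L])
  sn <- exp(theta[n_blocks + 2L])
  n <- length(y)
  K <- matern52(d2, ls, sf) + diag(sn^2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

#' Fit the Gaussian-process merit surrogate
#'
#' @param observations data frame holding the eight parameter columns plus
#'   the response column (at least 2 rows).
#' @param space parameter space the observations live in.
#' @param response name of the response column (default `"merit"`).
#' @param restarts number of seeded hyperparameter restarts (the first start
#'   is a fixed heuristic, the rest are random).
#' @param seed integer seed controlling the restarts.
#' @param init optional hyperparameter list (`lengthscales`, `signal_sd`,
#'   `noise_sd`) used as an additional warm start, e.g. from the previous
#'   refit inside a campaign.
#' @return an object of class `rxn_gp`.
#' @export
fit_gp <- function(observations, space, response = "merit", restarts = 5,
                   seed = 1, init = NULL) {
  y_raw <- observations[[response]]
  if (is.null(y_raw)) stop_rxnbo(sprintf("no '%s' column in observations", response),
                                 "rxnbo_config_error")
  if (length(y_raw) < 2L) stop_rxnbo("need at least 2 observations to fit", "rxnbo_config_error")
  encoding <- build_encoding(space)
  X <- encode_points(observations, encoding)
  ymean <- mean(y_raw)
  y <- y_raw - ymean
  if (stats::sd(y_raw) < 1e-12)
    warning("all responses identical: fitting at the noise floor", call. = FALSE)
  d2 <- block_sqdist(X, X, encoding)
  nb <- length(encoding$blocks)
  lower <- c(rep(log(0.05), nb), log(1e-3), log(1e-3))
  upper <- c(rep(log(50), nb), log(10), log(2))
  sd_y <- max(stats::sd(y_raw), 0.05)
  starts <- list(c(rep(log(1), nb), log(sd_y), log(0.1)))
  if (!is.null(init))
    starts <- c(starts, list(c(log(init$lengthscales), log(init$signal_sd),
                               log(init$noise_sd))))
  extra <- max(0L, restarts - length(starts))
  if (extra > 0) {
    rnd <- with_seed(seed, lapply(seq_len(extra), function(i)
      c(stats::runif(nb, log(0.3), log(5)),
        stats::runif(1, log(0.05), log(1)),
        stats::runif(1, log(0.02), log(0.5)))))
    starts <- c(starts, rnd)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), gp_nll, method = "L-BFGS-B",
                   lower = lower, upper = upper, d2 = d2, y = y, n_blocks = nb,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_rxnbo("GP hyperparameter optimization failed", "rxnbo_fit_error")
  theta <- best$par
  ls <- exp(theta[seq_len(nb)])
  sf <- exp(theta[nb + 1L])
  sn <- max(exp(theta[nb + 2L]), 1e-3)  # noise variance floored at 1e-6
  model <- structure(list(space = space, encoding = encoding, X = X, y_raw = y_raw,
                          ymean = ymean, lengthscales = ls, signal_sd = sf,
                          noise_sd = sn, nll = best$value, fitted = TRUE),
                     class = "rxn_gp")
  gp_factorize(model)
}

# (Re)compute the Cholesky factor and weights for the current data and
# hyperparameters.
gp_factorize <- function(model) {
  n <- nrow(model$X)
  d2 <- block_sqdist(model$X, model$X, model$encoding)
  K <- matern52(d2, model$lengthscales, model$signal_sd) + diag(model$noise_sd^2, n)
  L <- chol(K)  # upper triangular
  y <- model$y_raw - model$ymean
  model$L <- L
  model$alpha <- backsolve(L, forwardsolve(t(L), y))
  model
}

# Condition the model on additional (possibly fantasy) observations without
# re-optimizing hyperparameters; used by the constant-liar batch policy.
gp_condition <- function(model, points, y_new) {
  Xn <- encode_points(points, model$encoding)
  model$X <- rbind(model$X, Xn)
  model$y_raw <- c(model$y_raw, y_new)
  # keep the original prior mean: fantasies must not shift it
  gp_factorize(model)
}

#' Predictive mean and standard deviation of merit
#'
#' Standard Gaussian-process conditioning: far from the data the mean
#' reverts to the prior (the training mean) and the standard deviation to the
#' prior signal scale; at a training point the standard deviation is strictly
#' below the prior signal sd.
#'
#' @param object a fitted `rxn_gp`.
#' @param newdata data frame of candidate points (or an encoded matrix).
#' @param ... unused.
#' @return data frame with columns `mean` and `sd` (latent function, i.e.
#'   noise-free).
#' @export
predict.rxn_gp <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted)) stop_rxnbo("model is not fitted", "rxnbo_fit_error")
  Xs <- if (is.matrix(newdata)) newdata else encode_points(newdata, object$encoding)
  if (nrow(Xs) == 0L) return(data.frame(mean = numeric(0), sd = numeric(0)))
  d2 <- block_sqdist(object$X, Xs, object$encoding)
  Ks <- matern52(d2, object$lengthscales, object$signal_sd)  # n_train x n_new
  mu <- object$ymean + drop(crossprod(Ks, object$alpha))
  V <- forwardsolve(t(object$L), Ks)
  var <- pmax(object$signal_sd^2 - colSums(V^2), 0)
  data.frame(mean = mu, sd = sqrt(var))
}

#' @export
print.rxn_gp <- function(x, ...) {
  cat(sprintf("Gaussian-process merit surrogate (%d observations, %d features)\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  Matern-5/2, signal sd %.3f, noise sd %.3f, nll %.3f\n",
              x$signal_sd, x$noise_sd, x$nll))
  ls <- stats::setNames(round(x$lengthscales, 3), names(x$encoding$blocks))
  cat("  per-block length-scales:\n")
  print(ls)
  invisible(x)
}

#' Serialize / restore a fitted surrogate (JSON)
#'
#' Stores hyperparameters, the prior mean and the training records so a
#' campaign can be resumed with an identical model.
#'
#' @param model a fitted `rxn_gp`.
#' @param path JSON file path.
#' @export
write_gp <- function(model, path) {
  obs <- as.data.frame(decode_points(model$X, model$encoding))
  payload <- list(format = "rxnbo-gp", version = 1L,
                  lengthscales = model$lengthscales,
                  signal_sd = model$signal_sd, noise_sd = model$noise_sd,
                  ymean = model$ymean, y = model$y_raw, points = obs,
                  space = space_to_list(model$space))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "rxnbo-gp"))
    stop_rxnbo("not a serialized rxnbo GP model", "rxnbo_format_error")
  space <- space_from_list(payload$space)
  encoding <- build_encoding(space)
  points <- do.call(rbind, lapply(payload$points, function(row)
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)))
  X <- encode_points(points, encoding)
  model <- structure(list(space = space, encoding = encoding, X = X,
                          y_raw = as.numeric(unlist(payload$y)),
                          ymean = payload$ymean,
                          lengthscales = as.numeric(unlist(payload$lengthscales)),
                          signal_sd = payload$signal_sd, noise_sd = payload$noise_sd,
                          nll = NA_real_, fitted = TRUE),
                     class = "rxn_gp")
  gp_factorize(model)
}

space_to_list <- function(space) {
  lapply(space, function(p) list(name = p$name, kind = p$kind, options = p$options))
}

space_from_list <- function(lst) {
  lapply(lst, function(p) param_def(p$name, p$kind, unlist(p$options)))
}
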