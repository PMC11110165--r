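# One-hot / standardized feature encoding of grid points.
#
# Categorical parameters become one-hot blocks in the declared level order;
# ordinal-numeric parameters become single standardized columns. Location and
# scale are the mean and standard deviation of the *declared option levels*,
# so the encoding is a deterministic function of the parameter space alone
# and identical across campaigns on the same space.

#' Build the feature encoding for a parameter space
#'
#' @param space list of [param_def] objects.
#' @return an object of class `rxn_encoding` describing the column layout:
#'   one one-hot block per categorical parameter, one standardized column per
#'   numeric parameter; total column count = sum of categorical levels +
#'   number of numeric parameters.
#' @export
build_encoding <- function(space) {
  blocks <- list()
  col <- 0L
  for (p in space) {
    if (p$kind == "categorical") {
      idx <- col + seq_along(p$options)
      blocks[[p$name]] <- list(name = p$name, kind = p$kind,
                               levels = p$options, cols = idx)
      col <- col + length(p$options)
    } else {
      mu <- mean(p$options)
      sg <- stats::sd(p$options)
      if (!is.finite(sg) || sg == 0) sg <- 1
      blocks[[p$name]] <- list(name = p$name, kind = p$kind,
                               center = mu, scale = sg, cols = col + 1L)
      col <- col + 1L
    }
  }
  structure(list(blocks = blocks, ncol = col, space = space),
            class = "rxn_encoding")
}

#' Encode candidate points as a numeric feature matrix
#'
#' @param points data frame of candidate points (must contain every
#'   parameter column).
#' @param encoding an `rxn_encoding` (or a space, which is encoded first).
#' @return numeric matrix with one row per point; each categorical block has
#'   exactly one 1.
#' @export
encode_points <- function(points, encoding) {
  if (!inherits(encoding, "rxn_encoding")) encoding <- build_encoding(encoding)
  n <- nrow(points)
  X <- matrix(0, n, encoding$ncol)
  for (b in encoding$blocks) {
    v <- points[[b$name]]
    if (is.null(v)) stop_rxnbo(sprintf("points lack column '%s'", b$name),
                               "rxnbo_config_error")
    if (b$kind == "categorical") {
      j <- match(as.character(v), b$levels)
      if (anyNA(j))
        stop_rxnbo(sprintf("unknown level '%s' for '%s'",
                           as.character(v)[which(is.na(j))[1]], b$name),
                   "rxnbo_config_error")
      X[cbind(seq_len(n), b$cols[j])] <- 1
    } else {
      if (!all(v %in% space_param(encoding$space, b$name)$options))
        stop_rxnbo(sprintf("unknown level for '%s'", b$name), "rxnbo_config_error")
      X[, b$cols] <- (as.numeric(v) - b$center) / b$scale
    }
  }
  colnames(X) <- encoding_colnames(encoding)
  X
}

encoding_colnames <- function(encoding) {
  unlist(lapply(encoding$blocks, function(b)
    if (b$kind == "categorical") paste0(b$name, "=", b$levels) else b$name),
    use.names = FALSE)
}

#' Decode a feature matrix back to candidate points
#'
#' Inverse of [encode_points()]: categorical blocks by position of the 1,
#' numeric columns by unstandardizing and snapping to the nearest declared
#' level.
#'
#' @param X numeric feature matrix.
#' @param encoding an `rxn_encoding`.
#' @return data frame of candidate points.
#' @export
decode_points <- function(X, encoding) {
  if (!inherits(encoding, "rxn_encoding")) encoding <- build_encoding(encoding)
  out <- list()
  for (b in encoding$blocks) {
    if (b$kind == "categorical") {
      j <- apply(X[, b$cols, drop = FALSE], 1, which.max)
      out[[b$name]] <- b$levels[j]
    } else {
      raw <- X[, b$cols] * b$scale + b$center
      opts <- space_param(encoding$space, b$name)$options
      out[[b$name]] <- vapply(raw, function(r) opts[which.min(abs(opts - r))],
                              numeric(1))
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
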