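# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's random stream. All stochastic choices in the package (tie-breaks,
#' restarts, oracle noise) go through this helper, which is what makes
#' campaigns replayable from a single integer seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a campaign seed and a counter, kept inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647L)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# argmax with a seeded uniform tie-break; ties are values within 1e-12 of the
# maximum.
argmax_tiebreak <- function(x, seed) {
  m <- max(x)
  ties <- which(x >= m - 1e-12)
  if (length(ties) == 1L) return(ties)
  with_seed(seed, ties[sample.int(length(ties), 1L)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rxnbo <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rxnbo_error")))
}
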