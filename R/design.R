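# Experiment selection: greedy maximum-coverage initialization and
# acquisition-driven batch selection.

#' Configuration of the diversity initializer
#'
#' @param n_init number of initial experiments (11 by default, enough to
#'   cover every level of the four coverage fields on the default grid).
#' @param coverage_fields categorical parameters whose levels the initializer
#'   tries to cover; novelty is counted over these fields only, so the
#'   initializer is scale-free with respect to the numeric levels.
#' @param seed integer seed for tie-breaks.
#' @export
diversity_config <- function(n_init = 11,
                             coverage_fields = c("alkyne", "solvent",
                                                 "iodine_source", "catalyst"),
                             seed = 1) {
  if (n_init < 1) stop_rxnbo("n_init must be at least 1", "rxnbo_config_error")
  structure(list(n_init = as.integer(n_init), coverage_fields = coverage_fields,
                 seed = as.integer(seed)), class = "diversity_config")
}

#' Greedy maximum-coverage initial design
#'
#' Sequentially picks the grid point that explores the largest number of
#' not-yet-seen levels over the coverage fields; ties are broken by a seeded
#' uniform draw, so the design is deterministic given the seed.
#'
#' @param grid a `rxn_grid`.
#' @param config a [diversity_config].
#' @return a data frame of `n_init` distinct points (with `point_id`),
#'   carrying the per-step novelty counts as attribute `"novelty"`.
#' @export
greedy_diverse_init <- function(grid, config = diversity_config()) {
  sp <- grid_space(grid)
  fields <- config$coverage_fields
  bad <- setdiff(fields, space_names(sp))
  if (length(bad))
    stop_rxnbo(paste0("unknown coverage field(s): ", paste(bad, collapse = ", ")),
               "rxnbo_config_error")
  for (f in fields)
    if (space_param(sp, f)$kind != "categorical")
      stop_rxnbo(sprintf("coverage field '%s' is not categorical", f),
                 "rxnbo_config_error")
  n <- nrow(grid)
  if (config$n_init > n)
    stop_rxnbo("n_init exceeds the grid size", "rxnbo_config_error")
  seen <- stats::setNames(vector("list", length(fields)), fields)
  chosen <- integer(config$n_init)
  novelty <- integer(config$n_init)
  avail <- rep(TRUE, n)
  for (step in seq_len(config$n_init)) {
    nov <- rep(0L, n)
    for (f in fields)
      nov <- nov + as.integer(!(grid[[f]] %in% seen[[f]]))
    nov[!avail] <- -1L
    pick <- argmax_tiebreak(nov, child_seed(config$seed, step))
    chosen[step] <- pick
    novelty[step] <- nov[pick]
    avail[pick] <- FALSE
    for (f in fields)
      seen[[f]] <- union(seen[[f]], grid[[f]][pick])
  }
  out <- as.data.frame(grid)[chosen, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "novelty") <- novelty
  out
}

#' First design point after which all coverage levels are seen
#'
#' @param points ordered data frame of design points.
#' @param space the parameter space (for the full level rosters).
#' @param fields coverage fields.
#' @return the 1-based index of the first point at which every level of every
#'   field has appeared, or `NA` if coverage is never complete.
#' @export
coverage_complete_at <- function(points, space,
                                 fields = c("alkyne", "solvent",
                                            "iodine_source", "catalyst")) {
  totals <- vapply(fields, function(f) length(space_param(space, f)$options), integer(1))
  for (i in seq_len(nrow(points))) {
    done <- vapply(fields, function(f)
      length(unique(points[[f]][seq_len(i)])) == totals[[f]], logical(1))
    if (all(done)) return(i)
  }
  NA_integer_
}

#' Acquisition configuration
#'
#' @param xi exploration offset on the merit scale.
#' @param batch_size experiments per loop (2 by default: two reactors run in
#'   parallel).
#' @param liar constant-liar strategy for within-batch fantasies: the merit
#'   value imputed at an already-picked point (`"best"` uses the incumbent
#'   best merit).
#' @export
acquisition_config <- function(xi = 0.01, batch_size = 2, liar = "best") {
  if (xi < 0) stop_rxnbo("xi must be non-negative", "rxnbo_config_error")
  if (batch_size < 1) stop_rxnbo("batch_size must be at least 1", "rxnbo_config_error")
  structure(list(kind = "expected-improvement", xi = xi,
                 batch_size = as.integer(batch_size), liar = liar),
            class = "acquisition_config")
}

#' Expected improvement (maximization)
#'
#' `EI = (mean - best - xi) * Phi(z) + sd * phi(z)` with
#' `z = (mean - best - xi) / sd`; for `sd = 0` the limit
#' `max(0, mean - best - xi)` is returned. Always non-negative.
#'
#' @param mean,sd surrogate predictive mean and standard deviation (sd >= 0).
#' @param best_seen incumbent best merit.
#' @param xi exploration offset.
#' @return EI scores (vectorized).
#' @export
expected_improvement <- function(mean, sd, best_seen, xi = 0.01) {
  d <- mean - best_seen - xi
  ei <- pmax(d, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- d[pos] / sd[pos]
    ei[pos] <- d[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

#' Select the next batch of experiments
#'
#' Picks `batch_size` distinct unvisited candidates by expected improvement
#' with a constant-liar policy: after each pick a fantasy observation at the
#' incumbent best merit is imputed at the picked point, the surrogate is
#' re-conditioned (hyperparameters frozen) and EI is recomputed, which keeps
#' the batch diverse. Deterministic given the surrogate state and seed.
#'
#' @param model fitted `rxn_gp`.
#' @param candidates data frame of unvisited candidate points (visited points
#'   and converged substrates are excluded upstream).
#' @param best_seen incumbent best merit over the real history.
#' @param config an [acquisition_config].
#' @param seed integer seed for tie-breaks.
#' @return the selected points; if fewer candidates than `batch_size` remain,
#'   all of them, with attribute `"exhausted" = TRUE`.
#' @export
select_batch <- function(model, candidates, best_seen,
                         config = acquisition_config(), seed = 1) {
  if (nrow(candidates) == 0L)
    stop_rxnbo("infeasible space: no remaining candidates", "rxnbo_infeasible_space")
  exhausted <- nrow(candidates) < config$batch_size
  k <- min(config$batch_size, nrow(candidates))
  picked <- integer(0)
  m <- model
  for (j in seq_len(k)) {
    pred <- predict(m, candidates)
    ei <- expected_improvement(pred$mean, pred$sd, best_seen, config$xi)
    if (length(picked)) ei[picked] <- -Inf
    pick <- argmax_tiebreak(ei, child_seed(seed, j))
    picked <- c(picked, pick)
    if (j < k) {
      liar <- if (identical(config$liar, "best")) best_seen else as.numeric(config$liar)
      m <- gp_condition(m, candidates[pick, , drop = FALSE], liar)
    }
  }
  out <- candidates[picked, , drop = FALSE]
  rownames(out) <- NULL
  if (exhausted) attr(out, "exhausted") <- TRUE
  out
}
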