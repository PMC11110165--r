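# Closed-loop campaign orchestration.
#
# The loop mirrors an autonomous optimization campaign: a greedy
# maximum-coverage block of initial experiments, then repeated rounds of
# {fit surrogate on everything seen; drop candidates of converged
# substrates; pick a batch by constant-liar expected improvement; run the
# batch} until every substrate has surpassed the conversion threshold or the
# budget is spent. All randomness is derived from one campaign seed through
# fixed counters, so an interrupted campaign resumes onto the identical
# trajectory.

#' Campaign configuration
#'
#' @param merit a [merit_config].
#' @param stopping a [stopping_rule].
#' @param diversity a [diversity_config]; its seed is overridden by `seed`.
#' @param acquisition an [acquisition_config].
#' @param max_experiments total experiment budget (must be at least the size
#'   of the initial block).
#' @param seed campaign seed; drives initializer tie-breaks, surrogate
#'   restarts, acquisition tie-breaks and (for the synthetic oracle) the
#'   measurement noise.
#' @export
campaign_config <- function(merit = merit_config(), stopping = stopping_rule(),
                            diversity = diversity_config(),
                            acquisition = acquisition_config(),
                            max_experiments = 60, seed = 1) {
  if (max_experiments < diversity$n_init)
    stop_rxnbo("budget must cover the initial block", "rxnbo_config_error")
  structure(list(merit = merit, stopping = stopping, diversity = diversity,
                 acquisition = acquisition,
                 max_experiments = as.integer(max_experiments),
                 seed = as.integer(seed)),
            class = "campaign_config")
}

observation_row <- function(point, out, experiment, iteration) {
  row <- as.data.frame(point, stringsAsFactors = FALSE)
  row <- row[, setdiff(names(row), "point_id"), drop = FALSE]
  cbind(data.frame(experiment = experiment, iteration = iteration,
                   point_id = point$point_id %||% NA_integer_),
        row,
        data.frame(conversion = out$conversion, yield = out$yield,
                   raw_conversion = out$raw_conversion,
                   raw_yield = out$raw_yield, merit = out$merit))
}

#' Run a closed-loop optimization campaign
#'
#' @param oracle a function `(point, draw_seed) -> outcome list` (see
#'   [make_oracle()] for the synthetic landscape or [interactive_oracle()]
#'   for manual operation). Must be total on feasible points.
#' @param grid a `rxn_grid` of candidates.
#' @param config a [campaign_config].
#' @param state a saved campaign state from [load_state()] to resume from;
#'   `grid` and `config` are then taken from the state.
#' @return an object of class `rxn_campaign` with the observation history,
#'   the converged substrates, a convergence report and the stop reason
#'   (`"converged"`, `"budget"` or `"exhausted"`).
#' @export
run_campaign <- function(oracle, grid, config = campaign_config(), state = NULL) {
  if (!is.null(state)) {
    grid <- state$grid
    config <- state$config
    obs <- state$observations
    iteration <- state$iteration
    hyper <- state$hyper
  } else {
    obs <- NULL
    iteration <- 0L
    hyper <- NULL
  }
  seed <- config$seed
  sp <- grid_space(grid)
  alkynes <- space_param(sp, "alkyne")$options
  stop_reason <- NULL

  # --- initial block ---------------------------------------------------
  if (is.null(obs) || nrow(obs) == 0L) {
    div <- config$diversity
    div$seed <- seed
    init_pts <- greedy_diverse_init(grid, div)
    iteration <- 1L
    rows <- lapply(seq_len(nrow(init_pts)), function(i) {
      out <- oracle(init_pts[i, , drop = FALSE], child_seed(seed, 1000L + i))
      observation_row(init_pts[i, , drop = FALSE], out, i, iteration)
    })
    obs <- do.call(rbind, rows)
  }

  # --- optimization rounds ---------------------------------------------
  repeat {
    converged <- check_converged(obs, config$stopping)
    if (all(alkynes %in% converged)) { stop_reason <- "converged"; break }
    if (nrow(obs) >= config$max_experiments) { stop_reason <- "budget"; break }
    candidates <- as.data.frame(grid)
    candidates <- candidates[!(candidates$point_id %in% obs$point_id) &
                             !(candidates$alkyne %in% converged), , drop = FALSE]
    if (nrow(candidates) == 0L) { stop_reason <- "exhausted"; break }
    iteration <- iteration + 1L
    model <- fit_gp(obs, sp, restarts = if (is.null(hyper)) 5 else 3,
                    seed = child_seed(seed, 200L + iteration), init = hyper)
    hyper <- list(lengthscales = model$lengthscales,
                  signal_sd = model$signal_sd, noise_sd = model$noise_sd)
    best_seen <- max(obs$merit)
    acq <- config$acquisition
    acq$batch_size <- min(acq$batch_size, config$max_experiments - nrow(obs))
    batch <- select_batch(model, candidates, best_seen, acq,
                          seed = child_seed(seed, 500L + iteration))
    for (i in seq_len(nrow(batch))) {
      k <- nrow(obs) + 1L
      out <- oracle(batch[i, , drop = FALSE], child_seed(seed, 1000L + k))
      obs <- rbind(obs, observation_row(batch[i, , drop = FALSE], out, k, iteration))
    }
  }

  report <- replay_campaign(obs, config$stopping,
                            n_init = config$diversity$n_init,
                            batch_size = config$acquisition$batch_size,
                            alkynes = alkynes)
  structure(list(grid = grid, config = config, observations = obs,
                 converged = check_converged(obs, config$stopping),
                 iteration = iteration, report = report,
                 stop_reason = stop_reason, hyper = hyper),
            class = "rxn_campaign")
}

#' Scan a recorded history for per-substrate convergence
#'
#' A single pass over an ordered observation history records, for each
#' substrate, the first experiment whose conversion strictly surpasses the
#' threshold, the number of experiments spent on that substrate before it
#' converged, and the global stop: the experiment index completing the batch
#' in which the last substrate converged (campaigns run in batches, so the
#' partner experiment of a converging one still counts).
#'
#' @param observations data frame ordered by experiment with columns
#'   `alkyne` and `conversion`.
#' @param rule a [stopping_rule].
#' @param n_init size of the initial block (experiments `1..n_init` precede
#'   any batching).
#' @param batch_size experiments per optimization round.
#' @param alkynes substrates to report on; defaults to those observed.
#' @return an object of class `rxn_convergence_report`: data frame
#'   `per_alkyne` (columns `alkyne`, `first_surpassing`, `n_before`,
#'   `converged`), `last_convergence`, `stop_index` (NA while any substrate
#'   is open), `n_observations`.
#' @export
replay_campaign <- function(observations, rule = stopping_rule(),
                            n_init = 11, batch_size = 2, alkynes = NULL) {
  observations <- as.data.frame(observations)
  if (is.null(alkynes)) alkynes <- unique(as.character(observations$alkyne))
  n <- nrow(observations)
  hit <- observations$conversion > rule$conversion_threshold
  per <- lapply(alkynes, function(a) {
    idx <- which(observations$alkyne == a)
    first <- idx[hit[idx]][1]
    data.frame(alkyne = a,
               first_surpassing = if (is.na(first)) NA_integer_ else as.integer(first),
               n_before = if (is.na(first)) length(idx) else sum(idx < first),
               converged = !is.na(first), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  all_conv <- all(per$converged) && length(alkynes) > 0
  last <- if (all_conv) max(per$first_surpassing) else NA_integer_
  stop_index <- if (!all_conv) NA_integer_
    else if (last <= n_init) as.integer(n_init)
    else as.integer(n_init + batch_size * ceiling((last - n_init) / batch_size))
  structure(list(per_alkyne = per, last_convergence = last,
                 stop_index = stop_index, n_observations = n,
                 threshold = rule$conversion_threshold),
            class = "rxn_convergence_report")
}

#' @export
print.rxn_convergence_report <- function(x, ...) {
  cat(sprintf("Convergence scan (threshold: conversion > %.0f%%, %d observations)\n",
              100 * x$threshold, x$n_observations))
  print(x$per_alkyne, row.names = FALSE)
  if (!is.na(x$stop_index))
    cat(sprintf("last substrate converged at experiment %d; campaign stop at %d\n",
                x$last_convergence, x$stop_index))
  else cat("campaign still open: not all substrates converged\n")
  invisible(x)
}

#' @export
print.rxn_campaign <- function(x, ...) {
  cat(sprintf("Reaction-optimization campaign: %d experiments, %d iterations (%s)\n",
              nrow(x$observations), x$iteration, x$stop_reason %||% "running"))
  cat(sprintf("  best merit %.3f at experiment %d\n",
              max(x$observations$merit), which.max(x$observations$merit)))
  cat(sprintf("  converged substrates: %s\n",
              if (length(x$converged)) paste(x$converged, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
summary.rxn_campaign <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$report)
  best <- object$observations[which.max(object$observations$merit), , drop = FALSE]
  cat("\nBest conditions found:\n")
  print(best, row.names = FALSE)
  invisible(object$report)
}

#' @export
plot.rxn_campaign <- function(x, file = NULL, ...) {
  progress_chart(x$observations, rule = x$config$stopping,
                 n_init = x$config$diversity$n_init, file = file, ...)
}

#' Save / load a campaign state
#'
#' JSON serialization of everything needed to resume: the space and
#' constraints (the grid is rebuilt deterministically), the configuration,
#' the observation history and the surrogate warm start. Resuming a saved
#' campaign yields the same subsequent suggestions as an uninterrupted run.
#'
#' @param campaign an `rxn_campaign` (or the state list used internally).
#' @param path JSON file path.
#' @export
save_state <- function(campaign, path) {
  cfg <- campaign$config
  payload <- list(
    format = "rxnbo-campaign", version = 1L,
    space = space_to_list(grid_space(campaign$grid)),
    constraints = lapply(grid_constraints(campaign$grid), rule_to_list),
    config = list(w_yield = cfg$merit$w_yield,
                  w_conversion = cfg$merit$w_conversion,
                  conversion_threshold = cfg$stopping$conversion_threshold,
                  n_init = cfg$diversity$n_init,
                  coverage_fields = cfg$diversity$coverage_fields,
                  xi = cfg$acquisition$xi,
                  batch_size = cfg$acquisition$batch_size,
                  liar = cfg$acquisition$liar,
                  max_experiments = cfg$max_experiments, seed = cfg$seed),
    iteration = campaign$iteration,
    observations = campaign$observations,
    hyper = campaign$hyper)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        stop_rxnbo("corrupt campaign state file", "rxnbo_format_error"))
  if (!identical(payload$format, "rxnbo-campaign"))
    stop_rxnbo("not a rxnbo campaign state", "rxnbo_format_error")
  if (!identical(as.integer(payload$version), 1L))
    stop_rxnbo(sprintf("unsupported state version %s", payload$version),
               "rxnbo_format_error")
  space <- space_from_list(payload$space)
  constraints <- lapply(payload$constraints, rule_from_list)
  grid <- build_grid(space, constraints)
  c <- payload$config
  cfg <- campaign_config(
    merit = merit_config(c$w_yield, c$w_conversion),
    stopping = stopping_rule(c$conversion_threshold),
    diversity = diversity_config(c$n_init, unlist(c$coverage_fields), c$seed),
    acquisition = acquisition_config(c$xi, c$batch_size, c$liar),
    max_experiments = c$max_experiments, seed = c$seed)
  obs <- do.call(rbind, lapply(payload$observations, function(row)
    as.data.frame(lapply(row, function(v) v %||% NA), stringsAsFactors = FALSE,
                  check.names = FALSE)))
  hyper <- payload$hyper
  if (!is.null(hyper)) hyper$lengthscales <- as.numeric(unlist(hyper$lengthscales))
  list(grid = grid, config = cfg, observations = obs,
       iteration = as.integer(payload$iteration), hyper = hyper)
}
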