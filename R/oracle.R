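# Synthetic reaction oracle.
#
# A desk-scale stand-in for the robotic platform: a deterministic
# additive-effects landscape with route gates, plus Gaussian measurement
# noise. The defaults emulate the qualitative chemistry of the alkyne
# iodination: a broad chloramine-route optimum (polar solvents, temperatures
# at or below 65 C, at least stoichiometric iodide, no catalyst), uncatalyzed
# NIS reactions with both low conversion and low yield, and a deceptive
# NIS + PTSA region where strong acid hydrates the alkyne - high conversion,
# near-zero yield. The landscape is not a fit to any measured data set; it
# exists so optimizer behavior can be tested against a known ground truth.

#' Configuration of the synthetic iodination landscape
#'
#' All effects are additive on the fraction scale and composed before
#' clamping to \[0,1\]. Defaults were chosen once to reproduce the
#' qualitative structure above; see the package vignette for the rationale.
#'
#' @param chloramine_base base yield level of the chloramine route.
#' @param conversion_offset how much conversion exceeds yield on the
#'   chloramine route (side reactions consume substrate without product).
#' @param solvent_effect named additive yield bonus per solvent.
#' @param temp_plateau,temp_curvature temperature response: flat bonus up to
#'   45 C, quadratic penalty `-temp_curvature * (T - 45)^2` above.
#' @param salt_effect named bonus per iodide salt.
#' @param chloramine_eq_effect,salt_eq_effect bonuses for equivalents above
#'   stoichiometric, indexed by level.
#' @param alkyne_shift small per-substrate additive shifts (kept well below
#'   the main effects so optima transfer across substrates).
#' @param nis_uncat_conversion,nis_uncat_yield base levels of the uncatalyzed
#'   NIS route (diiodovinyl side product dominates).
#' @param nis_ptsa_conversion,nis_ptsa_yield base levels of the acid-
#'   catalyzed NIS route (electrophilic hydration: conversion without
#'   product).
#' @param noise_sd standard deviation of the Gaussian measurement noise added
#'   independently to conversion and yield (fraction units).
#' @export
landscape_config <- function(
    chloramine_base = 0.52,
    conversion_offset = 0.06,
    solvent_effect = c("MeOH" = 0.18, "CH3CN" = 0.16, "CH3CN/H2O" = 0.15,
                       "THF" = 0.06, "EtOAc" = 0.05, "DMF" = 0.04,
                       "DMSO" = 0.04, "1,4-dioxane" = 0.03, "DCE" = 0.02,
                       "DCM" = 0.01, "MTBE" = 0),
    temp_plateau = 0.10, temp_curvature = 1.4e-4,
    salt_effect = c("TBAI" = 0.10, "NaI" = 0.07, "KI" = 0.05, "NH4I" = 0.02),
    chloramine_eq_effect = c("1" = 0, "1.5" = 0.05, "2" = 0.07),
    salt_eq_effect = c("1" = 0, "1.5" = 0.04, "2" = 0.06),
    alkyne_shift = c("2-ethynyltoluene" = 0, "4-ethynyltoluene" = -0.01,
                     "1-chloro-2-ethynylbenzene" = -0.02,
                     "1-chloro-4-ethynylbenzene" = -0.03),
    nis_uncat_conversion = 0.14, nis_uncat_yield = 0.06,
    nis_ptsa_conversion = 0.70, nis_ptsa_yield = 0.02,
    noise_sd = 0.05) {
  stopifnot(noise_sd >= 0)
  cfg <- list(chloramine_base = chloramine_base,
              conversion_offset = conversion_offset,
              solvent_effect = solvent_effect,
              temp_plateau = temp_plateau, temp_curvature = temp_curvature,
              salt_effect = salt_effect,
              chloramine_eq_effect = chloramine_eq_effect,
              salt_eq_effect = salt_eq_effect,
              alkyne_shift = alkyne_shift,
              nis_uncat_conversion = nis_uncat_conversion,
              nis_uncat_yield = nis_uncat_yield,
              nis_ptsa_conversion = nis_ptsa_conversion,
              nis_ptsa_yield = nis_ptsa_yield,
              noise_sd = noise_sd)
  if (!all(is.finite(unlist(cfg))))
    stop_rxnbo("landscape effect magnitudes must be finite", "rxnbo_config_error")
  structure(cfg, class = "landscape_config")
}

check_route_consistency <- function(point) {
  nis <- point$iodine_source == "NIS"
  ok <- point$iodine_source_eq >= 1 &&
    ((nis && point$chloramine_eq == 0) ||
     (!nis && point$chloramine_eq >= 1 && point$catalyst == "none")) &&
    ((point$catalyst == "none") == (point$catalyst_eq == 0))
  if (!ok) stop_rxnbo("infeasible point passed to the synthetic oracle",
                      "rxnbo_infeasible_point")
  invisible(TRUE)
}

temp_response <- function(temp, config) {
  ifelse(temp <= 45, config$temp_plateau,
         config$temp_plateau - config$temp_curvature * (temp - 45)^2)
}

#' Noiseless response of the synthetic landscape
#'
#' @param point a feasible candidate point (named list or one-row data
#'   frame).
#' @param config a [landscape_config].
#' @return `list(conversion = , yield = )`, both clamped to \[0,1\].
#' @export
true_response <- function(point, config = landscape_config()) {
  point <- as.list(point)
  check_route_consistency(point)
  shift <- unname(config$alkyne_shift[point$alkyne])
  if (is.na(shift)) shift <- 0
  polar <- point$solvent %in% c("MeOH", "CH3CN", "CH3CN/H2O")
  if (point$iodine_source != "NIS") {
    solv <- unname(config$solvent_effect[point$solvent])
    if (is.na(solv)) solv <- 0  # solvents absent from the table are neutral
    g <- config$chloramine_base + solv +
      temp_response(point$temperature, config) +
      unname(config$salt_effect[point$iodine_source]) +
      unname(config$chloramine_eq_effect[as.character(point$chloramine_eq)]) +
      unname(config$salt_eq_effect[as.character(point$iodine_source_eq)]) +
      shift
    if (is.na(g)) stop_rxnbo("point level missing from landscape config",
                             "rxnbo_config_error")
    yield <- clamp01(g)
    conversion <- clamp01(g + config$conversion_offset)
  } else if (point$catalyst == "PTSA") {
    aq_bonus <- switch(point$solvent, "CH3CN/H2O" = 0.12, "CH3CN" = 0.08,
                       "MeOH" = 0.06, 0.02)
    conversion <- clamp01(config$nis_ptsa_conversion + aq_bonus +
                            (0.06 - 1.2e-4 * (point$temperature - 55)^2) +
                            0.04 * (point$catalyst_eq == 1) + shift)
    yield <- clamp01(config$nis_ptsa_yield + 0.02 * (point$solvent == "CH3CN/H2O"))
  } else if (point$catalyst == "AcOH") {
    hot <- point$temperature >= 75
    conversion <- clamp01(0.38 + 0.12 * hot + 0.02 * polar + shift)
    yield <- clamp01(0.28 + 0.10 * hot + 0.02 * polar + shift)
  } else {
    conversion <- clamp01(config$nis_uncat_conversion + 0.06 * polar +
                            0.05 * (point$temperature >= 75) +
                            0.02 * (point$iodine_source_eq >= 1.5) + shift)
    yield <- clamp01(config$nis_uncat_yield + 0.04 * polar +
                       0.02 * (point$temperature >= 75) + shift)
  }
  list(conversion = conversion, yield = yield)
}

#' Draw a noisy outcome from the synthetic landscape
#'
#' Adds independent Gaussian noise to the noiseless conversion and yield.
#' Raw values may fall slightly outside \[0,1\] - mimicking the calibration
#' offsets of a real assay - and are preserved; the merit is computed on the
#' clipped values. Deterministic for a given (point, draw_seed) pair.
#'
#' @param point feasible candidate point.
#' @param config a [landscape_config].
#' @param draw_seed integer seed of this draw.
#' @param merit a [merit_config].
#' @return an [outcome()] list.
#' @export
sample_outcome <- function(point, config = landscape_config(), draw_seed = 1,
                           merit = merit_config()) {
  tr <- true_response(point, config)
  if (config$noise_sd == 0) {
    eps <- c(0, 0)
  } else {
    eps <- with_seed(draw_seed, stats::rnorm(2, 0, config$noise_sd))
  }
  outcome(conversion = tr$conversion + eps[1], yield = tr$yield + eps[2],
          config = merit)
}

#' Noiseless scan of a grid: ground truth surfaces and the merit argmax
#'
#' @param config a [landscape_config].
#' @param grid a `rxn_grid`.
#' @param merit a [merit_config].
#' @return list with `surface` (the grid plus noiseless `conversion`,
#'   `yield`, `merit` columns), `argmax` (the best row, lowest `point_id` on
#'   ties) and `max_merit`.
#' @export
ground_truth <- function(config, grid, merit = merit_config()) {
  n <- nrow(grid)
  conv <- numeric(n); yld <- numeric(n)
  for (i in seq_len(n)) {
    tr <- true_response(grid[i, , drop = FALSE], config)
    conv[i] <- tr$conversion; yld[i] <- tr$yield
  }
  m <- compute_merit(yld, conv, merit)
  surface <- as.data.frame(grid)
  surface$conversion <- conv; surface$yield <- yld; surface$merit <- m
  best <- which(m >= max(m) - 1e-15)[1]  # deterministic tie-break: lowest index
  list(surface = surface, argmax = surface[best, , drop = FALSE], max_merit = m[best])
}

#' Wrap a landscape as a campaign oracle
#'
#' @param config a [landscape_config].
#' @param merit a [merit_config].
#' @return a function `(point, draw_seed) -> outcome`, the interface
#'   [run_campaign()] expects.
#' @export
make_oracle <- function(config = landscape_config(), merit = merit_config()) {
  force(config); force(merit)
  function(point, draw_seed) sample_outcome(point, config, draw_seed, merit)
}

#' Interactive oracle prompting the operator for measured outcomes
#'
#' For real use outside simulation: prints the suggested conditions and asks
#' for the measured conversion and yield on the console.
#'
#' @param merit a [merit_config].
#' @return an oracle function.
#' @export
interactive_oracle <- function(merit = merit_config()) {
  function(point, draw_seed) {
    cat("Run this experiment and report the measurements:\n")
    utils::str(as.list(point))
    conv <- as.numeric(readline("measured conversion (fraction): "))
    yld <- as.numeric(readline("measured yield (fraction): "))
    outcome(conv, yld, merit)
  }
}
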