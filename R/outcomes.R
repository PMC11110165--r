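# Conversion, yield and the weighted-sum merit.
#
# The HPLC diode-array detector reports peak areas; calibration curves map
# areas to concentrations, and the internal standard (added at the same molar
# amount as the starting alkyne) serves as the proxy for the alkyne
# concentration at t = 0. Conversion is the consumed fraction of the alkyne,
# yield the product concentration normalized by the internal standard, and
# merit the scalarization 0.9 * yield + 0.1 * conversion that the optimizer
# maximizes.

#' Linear calibration curve of a UV-detected analyte
#'
#' @param analyte identifier.
#' @param slope detector area units per mol/L; must be positive.
#' @param intercept detector area units. A nonzero intercept means small
#'   areas can map to (slightly) negative concentrations.
#' @export
calibration_curve <- function(analyte, slope, intercept = 0) {
  if (!is.numeric(slope) || slope <= 0)
    stop_rxnbo("calibration slope must be positive", "rxnbo_config_error")
  structure(list(analyte = analyte, slope = slope, intercept = intercept),
            class = "calibration_curve")
}

#' Concentration from a detector peak area
#'
#' Returns `(area - intercept) / slope`. The value may be negative when the
#' area falls below the curve intercept (a known calibration offset); a
#' warning is emitted and the caller decides about clipping.
#'
#' @param area detector area (>= 0).
#' @param curve a [calibration_curve].
#' @return concentration in mol/L.
#' @export
concentration_from_area <- function(area, curve) {
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0))
    warning(sprintf("area below calibration intercept for '%s': negative concentration returned",
                    curve$analyte), call. = FALSE)
  conc
}

#' Conversion of the starting alkyne
#'
#' `1 - C_SM / C_IS`: the internal standard concentration stands in for the
#' alkyne concentration at t = 0 because both were charged at the same molar
#' amount.
#'
#' @param c_sm residual starting-material concentration (mol/L).
#' @param c_is internal-standard concentration (mol/L), must be positive.
#' @return fraction consumed (can exceed \[0,1\] through measurement error).
#' @export
compute_conversion <- function(c_sm, c_is) {
  if (any(c_is <= 0)) stop_rxnbo("internal standard concentration must be positive",
                                 "rxnbo_measurement_error")
  1 - c_sm / c_is
}

#' Yield relative to the internal standard
#'
#' `C_product / C_IS`; raw values above 1 are possible (calibration offsets)
#' and are preserved, clipping happens only inside the merit.
#'
#' @param c_product product concentration (mol/L).
#' @inheritParams compute_conversion
#' @export
compute_yield <- function(c_product, c_is) {
  if (any(c_is <= 0)) stop_rxnbo("internal standard concentration must be positive",
                                 "rxnbo_measurement_error")
  c_product / c_is
}

#' Merit weighting configuration
#'
#' The default prioritizes yield (weight 0.9) over conversion (weight 0.1);
#' both inputs are clipped to \[0,1\] before weighting so merit is always a
#' number in \[0,1\].
#'
#' @param w_yield,w_conversion non-negative weights summing to one.
#' @export
merit_config <- function(w_yield = 0.9, w_conversion = 0.1) {
  if (w_yield < 0 || w_conversion < 0 || abs(w_yield + w_conversion - 1) > 1e-12)
    stop_rxnbo("merit weights must be non-negative and sum to 1", "rxnbo_config_error")
  structure(list(w_yield = w_yield, w_conversion = w_conversion,
                 clip_low = 0, clip_high = 1), class = "merit_config")
}

#' Weighted-sum merit of an outcome
#'
#' @param yield,conversion fractions (raw values allowed; clipped internally).
#' @param config a [merit_config].
#' @return merit in \[0,1\]; monotone non-decreasing in both arguments.
#' @export
compute_merit <- function(yield, conversion, config = merit_config()) {
  config$w_yield * clamp01(yield) + config$w_conversion * clamp01(conversion)
}

#' Assemble an outcome record
#'
#' Stores the raw (unclipped) measurements next to the clipped fractions and
#' the derived merit, so replayed histories are never destroyed by clipping.
#'
#' @param conversion,yield raw measured fractions.
#' @param config a [merit_config].
#' @return list with `conversion`, `yield` (clipped), `raw_conversion`,
#'   `raw_yield`, and `merit`.
#' @export
outcome <- function(conversion, yield, config = merit_config()) {
  list(conversion = clamp01(conversion), yield = clamp01(yield),
       raw_conversion = conversion, raw_yield = yield,
       merit = compute_merit(yield, conversion, config))
}

#' Per-substrate stopping rule
#'
#' A substrate has converged once any of its observations *surpasses* the
#' conversion threshold (strict inequality; 80 % by default).
#'
#' @param conversion_threshold fraction in (0, 1]. A threshold of exactly 1
#'   can never be surpassed (conversions are clipped to \[0,1\]), which turns
#'   off per-substrate stopping - useful for pure sample-efficiency
#'   benchmarks where the campaign should run out its budget.
#' @export
stopping_rule <- function(conversion_threshold = 0.80) {
  if (conversion_threshold <= 0 || conversion_threshold > 1)
    stop_rxnbo("conversion threshold must lie in (0,1]", "rxnbo_config_error")
  structure(list(conversion_threshold = conversion_threshold), class = "stopping_rule")
}

#' Converged substrates in an observation history
#'
#' @param history data frame of observations with columns `alkyne` and
#'   `conversion` (ordered or not; the set does not depend on order).
#' @param rule a [stopping_rule].
#' @return character vector of converged alkyne labels (empty for an empty
#'   history).
#' @export
check_converged <- function(history, rule = stopping_rule()) {
  if (is.null(history) || nrow(history) == 0L) return(character(0))
  hit <- history$conversion > rule$conversion_threshold
  sort(unique(as.character(history$alkyne[hit])))
}

#' Read / write observation records
#'
#' CSV with campaign metadata, the eight reaction parameters and the measured
#' objectives, one row per experiment.
#'
#' @param observations data frame of observations.
#' @param path file path.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(as.data.frame(observations), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE)
  need <- c("alkyne", "conversion", "yield")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_rxnbo(paste0("observation file is missing column(s): ",
                      paste(missing_cols, collapse = ", ")), "rxnbo_format_error")
  df
}
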