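# Parameter-space definition, chemistry constraints, and the feasible grid.
#
# The optimization domain is a finite grid: every reaction parameter is either
# categorical (alkyne, solvent, iodine source, catalyst) or an ordinal numeric
# level (equivalents, temperature in degrees C). Feasibility is decided by
# declarative constraint rules so that the grid is re-checkable and the
# builder itself contains no chemistry.

#' Define a single reaction parameter
#'
#' @param name identifier, e.g. `"solvent"`.
#' @param kind `"categorical"` or `"ordinal-numeric"`.
#' @param options allowed values in their declared order. For
#'   `"ordinal-numeric"` the levels must be strictly increasing (equivalents
#'   are dimensionless, temperature is in degrees C).
#' @return an object of class `param_def`.
#' @export
param_def <- function(name, kind = c("categorical", "ordinal-numeric"), options) {
  kind <- match.arg(kind)
  if (length(options) == 0L) stop_rxnbo("parameter options must be non-empty", "rxnbo_config_error")
  if (anyDuplicated(options)) stop_rxnbo("parameter options must be unique", "rxnbo_config_error")
  if (kind == "ordinal-numeric") {
    options <- as.numeric(options)
    if (any(diff(options) <= 0))
      stop_rxnbo("ordinal-numeric options must be strictly increasing", "rxnbo_config_error")
  } else {
    options <- as.character(options)
  }
  structure(list(name = name, kind = kind, options = options), class = "param_def")
}

space_names <- function(space) vapply(space, `[[`, character(1), "name")

#' Look up one parameter definition in a space
#'
#' @param space list of [param_def] objects.
#' @param name parameter name.
#' @return the matching `param_def`.
#' @export
space_param <- function(space, name) {
  i <- match(name, space_names(space))
  if (is.na(i)) stop_rxnbo(sprintf("unknown parameter '%s'", name), "rxnbo_config_error")
  space[[i]]
}

#' Constraint rules
#'
#' Four rule kinds cover the chemistry restrictions of the iodination grid:
#' a per-solvent maximum temperature (the boiling point), minimum equivalents
#' for reagents that take part in the chosen route, forbidden co-occurrences,
#' and conditional requirements.
#'
#' @param rule_id identifier used in error messages and provenance.
#' @param limits named numeric vector, solvent label -> maximum temperature
#'   (degrees C).
#' @param field,field_a,field_b,active_field,eq_field,if_field,then_field
#'   parameter names.
#' @param values_a,values_b,active_values,if_values,then_values option values.
#' @param min minimum allowed level of `eq_field` when `active_field` takes a
#'   value in `active_values`.
#' @return an object of class `constraint_rule`.
#' @name constraint_rules
NULL

# numeric payload values are stored as doubles so serialized rules compare
# identical after a JSON/YAML round-trip
norm_vals <- function(v) if (is.numeric(v)) as.numeric(v) else v

new_rule <- function(rule_id, rule_kind, payload) {
  structure(list(rule_id = rule_id, rule_kind = rule_kind, payload = payload),
            class = "constraint_rule")
}

#' @rdname constraint_rules
#' @export
max_temp_by_solvent <- function(limits, field = "temperature",
                                solvent_field = "solvent",
                                rule_id = "bp-cap") {
  if (any(limits <= 0)) stop_rxnbo("boiling points must be positive", "rxnbo_config_error")
  new_rule(rule_id, "max-temperature-by-solvent",
           list(field = field, solvent_field = solvent_field, limits = limits))
}

#' @rdname constraint_rules
#' @export
forbidden_combination <- function(field_a, values_a, field_b, values_b,
                                  rule_id = paste0("forbid-", field_a, "-", field_b)) {
  new_rule(rule_id, "forbidden-combination",
           list(field_a = field_a, values_a = norm_vals(values_a),
                field_b = field_b, values_b = norm_vals(values_b)))
}

#' @rdname constraint_rules
#' @export
min_equivalents_when_active <- function(active_field, active_values, eq_field, min,
                                        rule_id = paste0("min-", eq_field)) {
  new_rule(rule_id, "min-equivalents-when-active",
           list(active_field = active_field, active_values = norm_vals(active_values),
                eq_field = eq_field, min = as.numeric(min)))
}

#' @rdname constraint_rules
#' @export
conditional_requirement <- function(if_field, if_values, then_field, then_values,
                                    rule_id = paste0("require-", then_field)) {
  new_rule(rule_id, "conditional-requirement",
           list(if_field = if_field, if_values = norm_vals(if_values),
                then_field = then_field, then_values = norm_vals(then_values)))
}

rule_fields <- function(rule) {
  p <- rule$payload
  switch(rule$rule_kind,
    "max-temperature-by-solvent" = c(p$field, p$solvent_field),
    "forbidden-combination" = c(p$field_a, p$field_b),
    "min-equivalents-when-active" = c(p$active_field, p$eq_field),
    "conditional-requirement" = c(p$if_field, p$then_field))
}

check_rules_against_space <- function(space, constraints) {
  known <- space_names(space)
  for (r in constraints) {
    bad <- setdiff(rule_fields(r), known)
    if (length(bad))
      stop_rxnbo(sprintf("constraint '%s' references unknown field(s): %s",
                         r$rule_id, paste(bad, collapse = ", ")),
                 "rxnbo_config_error")
  }
  invisible(TRUE)
}

# Vectorized feasibility over the rows of a data frame of candidate points.
feasible_mask <- function(df, constraints) {
  ok <- rep(TRUE, nrow(df))
  for (r in constraints) {
    p <- r$payload
    ok <- ok & switch(r$rule_kind,
      "max-temperature-by-solvent" = {
        lim <- p$limits[as.character(df[[p$solvent_field]])]
        # solvents missing from the table are uncapped
        is.na(lim) | df[[p$field]] <= lim
      },
      "forbidden-combination" =
        !(df[[p$field_a]] %in% p$values_a & df[[p$field_b]] %in% p$values_b),
      "min-equivalents-when-active" =
        !(df[[p$active_field]] %in% p$active_values) | df[[p$eq_field]] >= p$min,
      "conditional-requirement" =
        !(df[[p$if_field]] %in% p$if_values) | df[[p$then_field]] %in% p$then_values)
  }
  ok
}

#' Is a candidate point feasible under a set of constraint rules?
#'
#' A total function on valid points: every rule is checked and the order of
#' evaluation has no effect.
#'
#' @param point a named list or one-row data frame with all parameters.
#' @param constraints list of [constraint_rules].
#' @return `TRUE` iff all rules pass.
#' @export
is_feasible <- function(point, constraints) {
  df <- as.data.frame(as.list(point), stringsAsFactors = FALSE)
  all(feasible_mask(df, constraints))
}

#' Enumerate the feasible parameter grid
#'
#' Takes the Cartesian product of the declared options in deterministic
#' lexicographic order (first declared parameter most significant) and keeps
#' the points passing every constraint.
#'
#' @param space list of [param_def] objects.
#' @param constraints list of constraint rules (may be empty).
#' @return a `rxn_grid`: a data frame with one column per parameter plus a
#'   stable integer `point_id`, carrying the space and constraints as
#'   attributes.
#' @export
build_grid <- function(space, constraints = list()) {
  check_rules_against_space(space, constraints)
  opts <- lapply(space, `[[`, "options")
  names(opts) <- space_names(space)
  # expand.grid varies the first column fastest; reverse so the first declared
  # parameter is the most significant sort key.
  df <- do.call(expand.grid, c(rev(opts), list(stringsAsFactors = FALSE)))
  df <- df[, names(opts), drop = FALSE]
  keep <- feasible_mask(df, constraints)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    stop_rxnbo("infeasible space: no candidate point satisfies the constraints",
               "rxnbo_infeasible_space")
  rownames(df) <- NULL
  df$point_id <- seq_len(nrow(df))
  structure(df, space = space, constraints = constraints,
            class = c("rxn_grid", "data.frame"))
}

#' Space and constraints carried by a grid
#'
#' @param grid a `rxn_grid`.
#' @return the parameter space / constraint list the grid was built from.
#' @export
grid_space <- function(grid) attr(grid, "space", exact = TRUE)

#' @rdname grid_space
#' @export
grid_constraints <- function(grid) attr(grid, "constraints", exact = TRUE)

#' Remove every point of one substrate from the grid
#'
#' Used for search-space contraction once a substrate has surpassed the
#' conversion stopping threshold; the surviving points keep their `point_id`.
#'
#' @param grid a `rxn_grid`.
#' @param alkyne a defined alkyne option label.
#' @param field name of the substrate column.
#' @return the contracted grid (possibly with zero rows).
#' @export
exclude_substrate <- function(grid, alkyne, field = "alkyne") {
  sp <- grid_space(grid)
  if (!alkyne %in% space_param(sp, field)$options)
    stop_rxnbo(sprintf("unknown %s label '%s'", field, alkyne), "rxnbo_config_error")
  out <- grid[grid[[field]] != alkyne, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, space = sp, constraints = grid_constraints(grid),
            class = c("rxn_grid", "data.frame"))
}

#' Read / write a grid as CSV
#'
#' The file format is one column per parameter with a header row of parameter
#' names, UTF-8, `"."` as the decimal separator. `write_grid` followed by
#' `read_grid` round-trips points and order exactly.
#'
#' @param grid a `rxn_grid`.
#' @param path file path.
#' @param space,constraints definition used to validate the file contents.
#' @return `read_grid` returns a `rxn_grid`.
#' @export
write_grid <- function(grid, path) {
  df <- as.data.frame(grid)[, space_names(grid_space(grid)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, space, constraints = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE)
  nm <- space_names(space)
  missing_cols <- setdiff(nm, names(df))
  if (length(missing_cols))
    stop_rxnbo(paste0("grid file is missing column(s): ",
                      paste(missing_cols, collapse = ", ")), "rxnbo_format_error")
  df <- df[, nm, drop = FALSE]
  for (p in space) {
    col <- df[[p$name]]
    if (p$kind == "ordinal-numeric") {
      col <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(col) | !col %in% p$options)
    } else {
      col <- as.character(col)
      bad <- which(!col %in% p$options)
    }
    if (length(bad))
      stop_rxnbo(sprintf("row %d: value '%s' is not an allowed option of '%s'",
                         bad[1], as.character(df[[p$name]][bad[1]]), p$name),
                 "rxnbo_format_error")
    df[[p$name]] <- col
  }
  df$point_id <- seq_len(nrow(df))
  structure(df, space = space, constraints = constraints,
            class = c("rxn_grid", "data.frame"))
}

#' @export
print.rxn_grid <- function(x, ...) {
  sp <- grid_space(x)
  cat(sprintf("Feasible reaction grid: %d points, %d parameters\n", nrow(x), length(sp)))
  for (p in sp)
    cat(sprintf("  %-18s %s (%d levels)\n", p$name, p$kind, length(p$options)))
  cat(sprintf("  constraints: %d rule(s)\n", length(grid_constraints(x))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Default iodination rosters

#' Solvent boiling points used by the temperature cap (degrees C)
#'
#' True boiling points; the aqueous acetonitrile mixture is capped by its
#' water component. Editable data, not code: pass a modified table to
#' [default_constraints()] to change the cap.
#'
#' @export
solvent_boiling_points <- c(
  "MeOH" = 64.7, "CH3CN" = 81.6, "CH3CN/H2O" = 100, "THF" = 66,
  "DMF" = 153, "DMSO" = 189, "DCM" = 39.6, "EtOAc" = 77.1,
  "1,4-dioxane" = 101.3, "MTBE" = 55.2, "DCE" = 83.5)

iodide_salts <- c("KI", "NaI", "TBAI", "NH4I")

#' Default parameter space for the alkyne iodination grid
#'
#' Eight parameters: substrate (four aromatic terminal alkynes), chloramine-B
#' equivalents, solvent, iodine source (four iodide salts for the chloramine
#' route plus N-iodosuccinimide), iodine-source equivalents, catalyst,
#' catalyst equivalents and temperature.
#'
#' Two solvent rosters are shipped. `"default"` carries 11 solvents
#' (acetonitrile both neat and as the aqueous mixture); `"campaign"` carries
#' the 10-solvent roster of the original autonomous iodination campaign,
#' whose feasible grid has exactly 12 036 points (4 substrates x 51 reagent
#' combinations x 59 solvent-temperature cells).
#'
#' @param roster `"default"` or `"campaign"`.
#' @return a list of [param_def] objects.
#' @export
default_space <- function(roster = c("default", "campaign")) {
  roster <- match.arg(roster)
  solvents <- c("MeOH", "CH3CN", "CH3CN/H2O", "THF", "DMF", "DMSO", "DCM",
                "EtOAc", "1,4-dioxane", "MTBE", "DCE")
  if (roster == "campaign") solvents <- setdiff(solvents, "CH3CN")
  list(
    param_def("alkyne", "categorical",
              c("2-ethynyltoluene", "4-ethynyltoluene",
                "1-chloro-2-ethynylbenzene", "1-chloro-4-ethynylbenzene")),
    param_def("chloramine_eq", "ordinal-numeric", c(0, 1, 1.5, 2)),
    param_def("solvent", "categorical", solvents),
    param_def("iodine_source", "categorical", c(iodide_salts, "NIS")),
    param_def("iodine_source_eq", "ordinal-numeric", c(0, 1, 1.5, 2)),
    param_def("catalyst", "categorical", c("PTSA", "AcOH", "none")),
    param_def("catalyst_eq", "ordinal-numeric", c(0, 0.1, 1)),
    param_def("temperature", "ordinal-numeric", c(25, 35, 45, 55, 65, 75, 85, 95))
  )
}

#' Default chemistry constraints for the iodination grid
#'
#' Encodes the route logic: temperatures are capped at the solvent boiling
#' point; the iodinating agent is always at least stoichiometric; N-iodo-
#' succinimide is never combined with chloramine salts; an iodide salt
#' requires the chloramine oxidant (at least 1 eq.); the acid catalysts used
#' with the NIS route are never combined with chloramine; and `catalyst =
#' "none"` pairs exactly with zero catalyst equivalents.
#'
#' @param boiling_points named vector of per-solvent maximum temperatures.
#' @return a list of constraint rules.
#' @export
default_constraints <- function(boiling_points = solvent_boiling_points) {
  list(
    max_temp_by_solvent(boiling_points),
    forbidden_combination("iodine_source", "NIS", "chloramine_eq", c(1, 1.5, 2),
                          rule_id = "no-NIS-with-chloramine"),
    forbidden_combination("catalyst", c("PTSA", "AcOH"), "chloramine_eq", c(1, 1.5, 2),
                          rule_id = "no-acid-catalyst-with-chloramine"),
    min_equivalents_when_active("iodine_source", iodide_salts, "chloramine_eq", 1,
                                rule_id = "chloramine-at-least-stoichiometric"),
    min_equivalents_when_active("iodine_source", c(iodide_salts, "NIS"),
                                "iodine_source_eq", 1,
                                rule_id = "iodine-source-at-least-stoichiometric"),
    conditional_requirement("catalyst", "none", "catalyst_eq", 0,
                            rule_id = "no-catalyst-means-zero-eq"),
    conditional_requirement("catalyst", c("PTSA", "AcOH"), "catalyst_eq", c(0.1, 1),
                            rule_id = "catalyst-needs-nonzero-eq")
  )
}

#' Build a default iodination grid
#'
#' @inheritParams default_space
#' @return a `rxn_grid` (13 260 points for the default roster, 12 036 for the
#'   campaign roster).
#' @export
default_grid <- function(roster = c("default", "campaign")) {
  roster <- match.arg(roster)
  build_grid(default_space(roster), default_constraints())
}

#' Which route does a grid point use?
#'
#' @param points data frame of candidate points.
#' @return `"NIS"` or `"chloramine"` per row.
#' @export
route_of <- function(points) {
  ifelse(points$iodine_source == "NIS", "NIS", "chloramine")
}

# ---------------------------------------------------------------------------
# YAML config round-trip (sections `parameters` and `constraints`)

#' Read / write a space-plus-constraints configuration
#'
#' The YAML layout has a `parameters` section (name/kind/options) and a
#' `constraints` section whose entries carry `rule_id`, `rule_kind` and an
#' explicit payload; no code is ever evaluated from a config file.
#'
#' @param path YAML file.
#' @param space,constraints objects to serialize.
#' @return `read_space_config` returns `list(space = , constraints = )`.
#' @export
read_space_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  space <- lapply(cfg$parameters, function(p)
    param_def(p$name, p$kind, unlist(p$options)))
  constraints <- lapply(cfg$constraints %||% list(), rule_from_list)
  check_rules_against_space(space, constraints)
  list(space = space, constraints = constraints)
}

#' @rdname read_space_config
#' @export
write_space_config <- function(space, constraints, path) {
  cfg <- list(
    parameters = lapply(space, function(p)
      list(name = p$name, kind = p$kind, options = as.list(p$options))),
    constraints = lapply(constraints, rule_to_list))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# plain-list (YAML/JSON-safe) views of a constraint rule
rule_to_list <- function(r) {
  p <- r$payload
  payload <- switch(r$rule_kind,
    "max-temperature-by-solvent" =
      list(field = p$field, solvent_field = p$solvent_field,
           limits = as.list(p$limits)),
    "forbidden-combination" =
      list(field_a = p$field_a, values_a = as.list(p$values_a),
           field_b = p$field_b, values_b = as.list(p$values_b)),
    "min-equivalents-when-active" =
      list(active_field = p$active_field,
           active_values = as.list(p$active_values),
           eq_field = p$eq_field, min = p$min),
    "conditional-requirement" =
      list(if_field = p$if_field, if_values = as.list(p$if_values),
           then_field = p$then_field, then_values = as.list(p$then_values)))
  list(rule_id = r$rule_id, rule_kind = r$rule_kind, payload = payload)
}

rule_from_list <- function(r) {
  p <- r$payload
  switch(r$rule_kind,
    "max-temperature-by-solvent" =
      max_temp_by_solvent(unlist(p$limits), field = p$field %||% "temperature",
                          solvent_field = p$solvent_field %||% "solvent",
                          rule_id = r$rule_id),
    "forbidden-combination" =
      forbidden_combination(p$field_a, unlist(p$values_a), p$field_b,
                            unlist(p$values_b), rule_id = r$rule_id),
    "min-equivalents-when-active" =
      min_equivalents_when_active(p$active_field, unlist(p$active_values),
                                  p$eq_field, p$min, rule_id = r$rule_id),
    "conditional-requirement" =
      conditional_requirement(p$if_field, unlist(p$if_values), p$then_field,
                              unlist(p$then_values), rule_id = r$rule_id),
    stop_rxnbo(sprintf("unknown rule_kind '%s'", r$rule_kind), "rxnbo_config_error"))
}
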