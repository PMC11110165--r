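test_that("unconstrained grids are plain Cartesian products", {
  sp <- list(param_def("a", "categorical", c("x", "y")),
             param_def("b", "ordinal-numeric", c(1, 2, 3)))
  g <- build_grid(sp)
  expect_equal(nrow(g), 6L)
  expect_equal(g$point_id, 1:6)
  # lexicographic: first declared parameter most significant
  expect_equal(g$a, rep(c("x", "y"), each = 3))
  expect_equal(g$b, rep(c(1, 2, 3), 2))
})

test_that("the boiling-point cap removes exactly the overheated cells", {
  sp <- tiny_space()
  rules <- list(max_temp_by_solvent(c("DCM" = 40, "DMF" = 153)))
  g <- build_grid(sp, rules)
  # brute-force enumeration of the 4 raw combinations against the rule
  bp <- c("DCM" = 40, "DMF" = 153)
  expected <- 0L
  for (s in c("DCM", "DMF")) for (temp in c(25, 95))
    if (temp <= bp[[s]]) expected <- expected + 1L
  expect_equal(nrow(g), expected)
  expect_equal(expected, 3L)
  expect_false(any(g$solvent == "DCM" & g$temperature == 95))
})

test_that("route-exclusion rules match the chemistry", {
  rules <- default_constraints()
  base <- list(alkyne = "2-ethynyltoluene", chloramine_eq = 1.5, solvent = "MeOH",
               iodine_source = "KI", iodine_source_eq = 1.5, catalyst = "none",
               catalyst_eq = 0, temperature = 25)
  # NIS and chloramine salts are never combined
  p <- base; p$iodine_source <- "NIS"
  expect_false(is_feasible(p, rules))
  # chloramine salts never meet the NIS-route acid catalyst
  p <- base; p$catalyst <- "PTSA"; p$catalyst_eq <- 0.1
  expect_false(is_feasible(p, rules))
  # stoichiometric chloramine (1 eq.) passes
  p <- base; p$chloramine_eq <- 1
  expect_true(is_feasible(p, rules))
  # an iodide salt without the oxidant is not a reaction
  p <- base; p$chloramine_eq <- 0
  expect_false(is_feasible(p, rules))
  # sub-stoichiometric iodine source is excluded
  p <- base; p$iodine_source_eq <- 0
  expect_false(is_feasible(p, rules))
  # evaluation order does not matter
  expect_true(is_feasible(base, rev(rules)))
})

test_that("builder count equals an independent brute-force enumeration", {
  sp <- toy_campaign_space()
  # restrict to <= 10k raw combinations
  sp[[3]] <- param_def("solvent", "categorical", c("MeOH", "THF", "DCM"))
  rules <- default_constraints()
  g <- build_grid(sp, rules)
  bp <- solvent_boiling_points
  salts <- c("KI", "NaI", "TBAI", "NH4I")
  count <- 0L
  for (alk in sp[[1]]$options) for (chl in sp[[2]]$options)
    for (sol in sp[[3]]$options) for (src in sp[[4]]$options)
      for (se in sp[[5]]$options) for (cat in sp[[6]]$options)
        for (ce in sp[[7]]$options) for (temp in sp[[8]]$options) {
          ok <- temp <= bp[[sol]] &&
            se >= 1 &&
            !(src == "NIS" && chl >= 1) &&
            !(src %in% salts && chl < 1) &&
            !(cat %in% c("PTSA", "AcOH") && chl >= 1) &&
            ((cat == "none") == (ce == 0))
          if (ok) count <- count + 1L
        }
  expect_equal(nrow(g), count)
  # every returned point re-checks as feasible
  expect_true(all(vapply(seq_len(nrow(g)), function(i)
    is_feasible(g[i, ], rules), logical(1))))
})

test_that("grid construction is deterministic", {
  g1 <- build_grid(toy_campaign_space(), default_constraints())
  g2 <- build_grid(toy_campaign_space(), default_constraints())
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("constraints referencing unknown fields are rejected", {
  sp <- tiny_space()
  bad <- list(forbidden_combination("nope", "x", "solvent", "DCM"))
  expect_error(build_grid(sp, bad), class = "rxnbo_config_error")
})

test_that("an over-constrained space fails loudly", {
  sp <- tiny_space()
  rules <- list(max_temp_by_solvent(c("DCM" = 10, "DMF" = 10)))
  expect_error(build_grid(sp, rules), class = "rxnbo_infeasible_space")
})

test_that("substrate exclusion preserves other points and is idempotent", {
  g <- toy_campaign_grid()
  alks <- space_param(grid_space(g), "alkyne")$options
  per <- table(g$alkyne)
  g1 <- exclude_substrate(g, alks[1])
  expect_equal(nrow(g1), nrow(g) - per[[alks[1]]])
  expect_false(alks[1] %in% g1$alkyne)
  # surviving point ids unchanged
  expect_true(all(g1$point_id %in% g$point_id))
  expect_identical(as.data.frame(exclude_substrate(g1, alks[1])), as.data.frame(g1))
  # exclusion commutes across distinct substrates
  a12 <- exclude_substrate(exclude_substrate(g, alks[1]), alks[2])
  a21 <- exclude_substrate(exclude_substrate(g, alks[2]), alks[1])
  expect_identical(as.data.frame(a12), as.data.frame(a21))
  # excluding an absent label is the identity
  expect_identical(as.data.frame(exclude_substrate(g1, alks[1])), as.data.frame(g1))
  # removing every substrate empties the grid and the next suggestion fails
  ge <- g
  for (a in alks) ge <- exclude_substrate(ge, a)
  expect_equal(nrow(ge), 0L)
  expect_error(greedy_diverse_init(ge, diversity_config(n_init = 1)),
               class = "rxnbo_config_error")
  expect_error(unknown <- exclude_substrate(g, "not-an-alkyne"),
               class = "rxnbo_config_error")
})

test_that("grid files round-trip exactly and are validated", {
  g <- build_grid(tiny_space(), list(max_temp_by_solvent(c("DCM" = 40, "DMF" = 153))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, f)
  g2 <- read_grid(f, tiny_space(), grid_constraints(g))
  expect_identical(as.data.frame(g2), as.data.frame(g))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_grid(g2, f2)
  expect_identical(readLines(f), readLines(f2))
  # a value outside the declared options is rejected with its row index
  tab <- utils::read.csv(f, check.names = FALSE)
  tab$solvent[2] <- "acetone"
  utils::write.csv(tab, f2, row.names = FALSE)
  expect_error(read_grid(f2, tiny_space()), regexp = "row 2",
               class = "rxnbo_format_error")
  # a missing parameter column is a format error
  utils::write.csv(tab[, "solvent", drop = FALSE], f2, row.names = FALSE)
  expect_error(read_grid(f2, tiny_space()), class = "rxnbo_format_error")
})

test_that("YAML configs reproduce the grid and ship with the package", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_space_config(toy_campaign_space(), default_constraints(), f)
  cfg <- read_space_config(f)
  expect_identical(as.data.frame(build_grid(cfg$space, cfg$constraints)),
                   as.data.frame(toy_campaign_grid()))
  for (roster in c("default", "campaign")) {
    shipped <- system.file("extdata", paste0("space_", roster, ".yaml"),
                           package = "rxnbo")
    expect_true(nzchar(shipped))
    cfg <- read_space_config(shipped)
    expect_identical(as.data.frame(build_grid(cfg$space, cfg$constraints)),
                     as.data.frame(default_grid(roster)))
  }
})
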