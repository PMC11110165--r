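toy_config <- function(seed = 1, budget = 40, threshold = 0.8) {
  campaign_config(stopping = stopping_rule(threshold),
                  diversity = diversity_config(n_init = 8),
                  max_experiments = budget, seed = seed)
}

test_that("an always-converting oracle stops within the initial block", {
  g <- toy_campaign_grid()
  oracle <- function(point, draw_seed) outcome(conversion = 1, yield = 1)
  camp <- run_campaign(oracle, g, toy_config())
  expect_identical(camp$stop_reason, "converged")
  expect_lte(camp$report$stop_index, 8L)
  expect_setequal(camp$converged, space_param(grid_space(g), "alkyne")$options)
})

test_that("a never-converting oracle exhausts the budget", {
  g <- toy_campaign_grid()
  oracle <- function(point, draw_seed) outcome(conversion = 0, yield = 0)
  # the all-identical responses make every surrogate refit warn about the
  # noise floor; that is the documented degenerate-fit behavior
  camp <- suppressWarnings(run_campaign(oracle, g, toy_config(budget = 14)))
  expect_identical(camp$stop_reason, "budget")
  expect_identical(camp$converged, character(0))
  expect_equal(nrow(camp$observations), 14L)
})

test_that("campaigns never repeat points nor revisit converged substrates", {
  g <- toy_campaign_grid()
  for (seed in 1:3) {
    camp <- run_campaign(make_oracle(), g, toy_config(seed = seed))
    obs <- camp$observations
    expect_equal(anyDuplicated(obs$point_id), 0L)
    # after a substrate converges, later batches never carry it (its batch
    # partner, selected in the same round, is the only allowed straggler)
    for (a in camp$converged) {
      idx <- which(obs$alkyne == a & obs$conversion > 0.8)[1]
      later <- obs[obs$alkyne == a & obs$experiment > obs$experiment[idx], ]
      expect_true(all(later$iteration == obs$iteration[idx]))
    }
  }
})

test_that("identical seeds reproduce identical campaigns", {
  g <- toy_campaign_grid()
  c1 <- run_campaign(make_oracle(), g, toy_config(seed = 42, budget = 20))
  c2 <- run_campaign(make_oracle(), g, toy_config(seed = 42, budget = 20))
  expect_identical(c1$observations, c2$observations)
  c3 <- run_campaign(make_oracle(), g, toy_config(seed = 43, budget = 20))
  expect_false(identical(c1$observations$point_id, c3$observations$point_id))
})

test_that("saved campaigns resume onto the uninterrupted trajectory", {
  g <- toy_campaign_grid()
  full <- run_campaign(make_oracle(), g, toy_config(seed = 7, budget = 16, threshold = 1))
  half <- run_campaign(make_oracle(), g, toy_config(seed = 7, budget = 12, threshold = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_state(half, f)
  st <- load_state(f)
  # state round-trips
  expect_equal(st$observations$point_id, half$observations$point_id)
  expect_equal(st$observations$merit, half$observations$merit, tolerance = 1e-12)
  expect_identical(as.data.frame(st$grid), as.data.frame(g))
  # lift the budget and resume: same experiments as the uninterrupted run
  st$config$max_experiments <- 16L
  resumed <- run_campaign(make_oracle(), state = st)
  expect_equal(resumed$observations$point_id, full$observations$point_id)
  expect_equal(resumed$observations$merit, full$observations$merit, tolerance = 1e-9)
  # corrupt files are rejected without partial state
  writeLines("{ not json", f)
  expect_error(load_state(f), class = "rxnbo_format_error")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "rxnbo-campaign", version = 99), f2,
                       auto_unbox = TRUE)
  expect_error(load_state(f2), class = "rxnbo_format_error")
})

test_that("the replay scanner matches a brute-force double loop", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    h <- data.frame(alkyne = sample(paste0("alk", 1:4), n, TRUE),
                    conversion = runif(n, 0, 1.0))
    got <- replay_campaign(h, stopping_rule(0.8), n_init = 11, batch_size = 2)
    want <- bf_replay(h, 0.8)
    for (a in names(want$first)) {
      row <- got$per_alkyne[got$per_alkyne$alkyne == a, ]
      expect_equal(row$first_surpassing, unname(want$first[a]))
      expect_equal(row$n_before, unname(want$n_before[a]))
    }
    if (all(!is.na(want$first))) {
      last <- max(want$first)
      expect_equal(got$last_convergence, last)
      expect_equal(got$stop_index,
                   if (last <= 11) 11L else 11L + 2L * as.integer(ceiling((last - 11) / 2)))
    } else {
      expect_true(is.na(got$stop_index))
    }
  }
  # single converged observation: index 1, everything else open
  h1 <- data.frame(alkyne = "alk1", conversion = 0.95)
  r1 <- replay_campaign(h1, alkynes = paste0("alk", 1:4))
  expect_equal(r1$per_alkyne$first_surpassing[1], 1L)
  expect_true(all(!r1$per_alkyne$converged[-1]))
  expect_true(is.na(r1$stop_index))
})

test_that("the optimizer converges all substrates faster than random search", {
  g <- toy_campaign_grid()
  cfg <- landscape_config()
  n_seeds <- 20
  budget <- 60
  bo <- vapply(seq_len(n_seeds), function(s) {
    camp <- run_campaign(make_oracle(cfg), g, toy_config(seed = s, budget = budget))
    if (identical(camp$stop_reason, "converged")) nrow(camp$observations)
    else budget + 1
  }, numeric(1))
  ws <- getFromNamespace("with_seed", "rxnbo")
  alks <- space_param(grid_space(g), "alkyne")$options
  rs <- vapply(seq_len(n_seeds), function(s) {
    idx <- ws(5000 + s, sample.int(nrow(g), budget))
    conv <- vapply(seq_along(idx), function(k)
      sample_outcome(g[idx[k], ], cfg, draw_seed = s * 977 + k)$conversion,
      numeric(1))
    alk <- g$alkyne[idx]
    done <- vapply(seq_along(idx), function(k)
      all(alks %in% unique(alk[seq_len(k)][conv[seq_len(k)] > 0.8])), logical(1))
    k <- which(done)[1]
    if (is.na(k)) budget + 1 else k
  }, numeric(1))
  expect_lt(stats::median(bo), stats::median(rs))
})
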