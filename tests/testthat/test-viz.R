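pooled_49 <- function() pool_campaign_histories(synthetic_campaign_histories())

test_that("t-SNE embeds the pooled campaigns reproducibly", {
  pool <- pooled_49()
  sp <- default_space("campaign")
  map <- embed_points(pool, sp, exclude = "alkyne", perplexity = 10, seed = 5,
                      max_iter = 400)
  expect_equal(nrow(map$coords), 49L)
  expect_true(all(is.finite(unlist(map$coords))))
  map2 <- embed_points(pool, sp, exclude = "alkyne", perplexity = 10, seed = 5,
                       max_iter = 400)
  expect_identical(map$coords, map2$coords)
  expect_error(embed_points(pool[1:3, ], sp), class = "rxnbo_config_error")
  expect_error(embed_points(pool[1:8, ], sp, perplexity = 10),
               class = "rxnbo_config_error")
})

test_that("points identical up to the excluded field land together", {
  sp <- default_space("campaign")
  g <- default_grid("campaign")
  ws <- getFromNamespace("with_seed", "rxnbo")
  pts <- as.data.frame(g)[ws(3, sample.int(nrow(g), 24)), ]
  # rows 1 and 2: same conditions, different substrate
  pts[2, ] <- pts[1, ]
  pts$alkyne[2] <- setdiff(space_param(sp, "alkyne")$options, pts$alkyne[1])[1]
  map <- embed_points(pts, sp, exclude = "alkyne", perplexity = 5, seed = 9,
                      max_iter = 400)
  D <- as.matrix(stats::dist(map$coords))
  pair <- D[1, 2]
  expect_lte(pair, stats::quantile(D[upper.tri(D)], 0.05))
})

test_that("contours interpolate linearly and respect the value range", {
  pool <- pooled_49()
  sp <- default_space("campaign")
  map <- embed_points(pool, sp, seed = 2, max_iter = 300)
  vals <- pool$merit
  surf <- contour_from_values(map, vals, field = "merit", resolution = 60)
  expect_equal(dim(surf$z), c(60L, 60L))
  expect_true(all(is.finite(surf$z)))
  # bounded by the inputs (linear inside the hull, nearest outside)
  expect_gte(min(surf$z), min(vals) - 1e-9)
  expect_lte(max(surf$z), max(vals) + 1e-9)
  # the surface reproduces the inputs at the embedded points
  at_pts <- interp_scattered(map$coords$x, map$coords$y, vals,
                             map$coords$x, map$coords$y)
  expect_equal(at_pts, vals, tolerance = 1e-6)
  # constant field -> constant surface
  flat <- contour_from_values(map, rep(0.4, 49), resolution = 40)
  expect_equal(range(flat$z), c(0.4, 0.4))
  expect_error(contour_from_values(map, vals[1:5]), class = "rxnbo_config_error")
  # degenerate geometry is refused
  expect_error(interp_scattered(rep(1, 5), rep(2, 5), 1:5, 1, 2),
               class = "rxnbo_degenerate_geometry")
})

test_that("surrogate contours cover unlabelled points too", {
  pool <- pooled_49()
  sp <- default_space("campaign")
  map <- embed_points(pool, sp, seed = 4, max_iter = 300)
  # model trained on the 11 labelled markers only
  m11 <- fit_gp(pool[1:11, ], sp, seed = 1)
  surf <- surrogate_contour(map, m11, resolution = 40)
  expect_true(all(is.finite(surf$z)))
  expect_equal(length(surf$values), 49L)   # defined at every embedded point
  # trained on everything, the predicted field tracks the true one closely
  mall <- fit_gp(pool, sp, seed = 1)
  pred <- predict(mall, pool)
  expect_true(all(abs(pred$mean - pool$merit) <= 2 * mall$noise_sd + 1e-8))
  expect_error(surrogate_contour(map, structure(list(fitted = FALSE),
                                                class = "rxn_gp")),
               class = "rxnbo_fit_error")
})

test_that("surrogate ranking improves as the campaign grows", {
  sp <- toy_campaign_space()
  g <- toy_campaign_grid()
  cfg <- landscape_config()
  ws <- getFromNamespace("with_seed", "rxnbo")
  deltas <- vapply(1:20, function(s) {
    idx <- ws(700 + s, sample.int(nrow(g), 49))
    obs <- as.data.frame(g)[idx, ]
    obs$merit <- vapply(seq_len(49), function(i)
      sample_outcome(obs[i, ], cfg, draw_seed = s * 1000 + i)$merit, numeric(1))
    truth <- vapply(seq_len(49), function(i) {
      tr <- true_response(obs[i, ], cfg)
      compute_merit(tr$yield, tr$conversion)
    }, numeric(1))
    held <- 24:49
    rho <- function(k) {
      m <- fit_gp(obs[1:k, ], sp, seed = s, restarts = 2)
      stats::cor(predict(m, obs[held, ])$mean, truth[held], method = "spearman")
    }
    rho(23) - rho(11)
  }, numeric(1))
  expect_gte(stats::median(deltas), 0)
})

test_that("charts render to image files without touching state", {
  h <- synthetic_campaign_histories()$light
  f1 <- withr::local_tempfile(fileext = ".png")
  before <- h
  progress_chart(h, file = f1)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(h, before)
  # single observation still plots
  f2 <- withr::local_tempfile(fileext = ".png")
  progress_chart(h[1, ], file = f2)
  expect_true(file.size(f2) > 0)
  # parallel coordinates: 16 converged traces across the pooled campaigns
  f3 <- withr::local_tempfile(fileext = ".png")
  pc <- parallel_coordinates(pooled_49(), converged_only = TRUE, file = f3)
  expect_equal(pc$n_traces, 16L)
  expect_true(file.size(f3) > 0)
  # all-below-threshold history draws an empty chart with a warning
  low <- h[h$conversion <= 0.8, ]
  f4 <- withr::local_tempfile(fileext = ".png")
  expect_warning(pc0 <- parallel_coordinates(low, converged_only = TRUE, file = f4),
                 "no converged")
  expect_equal(pc0$n_traces, 0L)
})
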