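# Interpretability layer: contour maps over the t-SNE plane, the
# conversion progress chart and parallel coordinates. Chart functions only
# read campaign data - they never modify state - and write standard image
# files when given a file name.

#' Contour surface over an embedding
#'
#' Interpolates per-point scalar values (true merit, predicted merit,
#' conversion or yield) onto a regular mesh over the embedding bounding box:
#' linear interpolation within the convex hull, nearest-neighbor fill
#' outside so the map is visually complete.
#'
#' @param map an `rxn_embedding` from [embed_points()].
#' @param values one scalar per embedded point.
#' @param field name of the scalar field (used for titles).
#' @param resolution mesh nodes per axis.
#' @return an object of class `rxn_contour` with mesh vectors `x`, `y`,
#'   elevation matrix `z` (length(x) rows), the embedded coordinates and the
#'   input values.
#' @export
contour_from_values <- function(map, values, field = "merit", resolution = 200) {
  co <- map$coords
  if (length(values) != nrow(co))
    stop_rxnbo("one value per embedded point is required", "rxnbo_config_error")
  padx <- diff(range(co$x)) * 0.05 + 1e-9
  pady <- diff(range(co$y)) * 0.05 + 1e-9
  gx <- seq(min(co$x) - padx, max(co$x) + padx, length.out = resolution)
  gy <- seq(min(co$y) - pady, max(co$y) + pady, length.out = resolution)
  mesh <- expand.grid(x = gx, y = gy)
  z <- interp_scattered(co$x, co$y, values, mesh$x, mesh$y)
  structure(list(x = gx, y = gy, z = matrix(z, nrow = resolution),
                 field = field, coords = co, values = values),
            class = "rxn_contour")
}

#' @export
plot.rxn_contour <- function(x, file = NULL, ...) {
  if (!is.null(file)) { grDevices::png(file, width = 900, height = 700); on.exit(grDevices::dev.off()) }
  graphics::image(x$x, x$y, x$z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "t-SNE 1", ylab = "t-SNE 2", main = x$field, ...)
  graphics::contour(x$x, x$y, x$z, add = TRUE, col = "grey30", lwd = 0.5)
  graphics::points(x$coords$x, x$coords$y, pch = 21, bg = "white")
  invisible(x)
}

#' Surrogate-prediction contour over an embedding
#'
#' Elevation is the surrogate predictive mean at *every* embedded point
#' (trained and untrained alike), which allows a side-by-side comparison of
#' the model's belief with the true objective map.
#'
#' @param map an `rxn_embedding`.
#' @param model a fitted `rxn_gp` (typically trained on a subset of the
#'   embedded points - the labelled markers).
#' @param resolution mesh nodes per axis.
#' @return an `rxn_contour` of the predicted merit.
#' @export
surrogate_contour <- function(map, model, resolution = 200) {
  if (!isTRUE(model$fitted)) stop_rxnbo("model is not fitted", "rxnbo_fit_error")
  pred <- predict(model, map$points)
  contour_from_values(map, pred$mean, field = "predicted merit",
                      resolution = resolution)
}

#' Conversion progress chart of a campaign
#'
#' Conversion against experiment index: the stopping threshold as a dotted
#' line, the initial block shaded, substrates encoded by marker shape and
#' the reaction route by color (NIS green, chloramine blue).
#'
#' @param history observation data frame (`experiment`, `alkyne`,
#'   `iodine_source`, `conversion`).
#' @param rule a [stopping_rule] (drawn as the threshold line).
#' @param n_init size of the shaded initial block.
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @return invisibly, the plotted data.
#' @export
progress_chart <- function(history, rule = stopping_rule(), n_init = 11,
                           file = NULL) {
  if (nrow(history) == 0L) stop_rxnbo("empty history", "rxnbo_config_error")
  if (!is.null(file)) { grDevices::png(file, width = 900, height = 600); on.exit(grDevices::dev.off()) }
  alks <- unique(history$alkyne)
  pchs <- stats::setNames((21:25)[seq_along(alks)], alks)
  cols <- ifelse(route_of(history) == "NIS", "forestgreen", "steelblue")
  graphics::plot(history$experiment, history$conversion, type = "n",
                 xlab = "experiment", ylab = "conversion",
                 ylim = c(0, max(1, history$conversion)),
                 main = "Conversion progress")
  graphics::rect(0.5, -0.1, n_init + 0.5, 1.2, col = "grey92", border = NA)
  graphics::abline(h = rule$conversion_threshold, lty = 3)
  graphics::points(history$experiment, history$conversion,
                   pch = pchs[history$alkyne], bg = cols, col = "black")
  graphics::legend("bottomright", legend = alks, pch = pchs, bty = "n", cex = 0.8)
  invisible(history)
}

#' Parallel-coordinates chart of an observation history
#'
#' One trace per experiment across the parameter columns followed by the
#' objectives and the merit; traces are shaded by merit (darker = better).
#' With `converged_only` only experiments whose conversion surpasses the
#' stopping threshold are drawn.
#'
#' @param history observation data frame.
#' @param converged_only draw only converged experiments.
#' @param rule a [stopping_rule].
#' @param file optional PNG path.
#' @return invisibly, a list with `n_traces` and the column order.
#' @export
parallel_coordinates <- function(history, converged_only = FALSE,
                                 rule = stopping_rule(), file = NULL) {
  if (nrow(history) == 0L) stop_rxnbo("empty history", "rxnbo_config_error")
  params <- c("alkyne", "chloramine_eq", "solvent", "iodine_source",
              "iodine_source_eq", "catalyst", "catalyst_eq", "temperature")
  params <- intersect(params, names(history))
  cols <- c(params, intersect(c("conversion", "yield", "merit"), names(history)))
  df <- history
  if (converged_only)
    df <- df[df$conversion > rule$conversion_threshold, , drop = FALSE]
  n <- nrow(df)
  if (!is.null(file)) { grDevices::png(file, width = 1000, height = 600); on.exit(grDevices::dev.off()) }
  scaled <- sapply(cols, function(cn) {
    v <- df[[cn]]
    if (is.numeric(v)) {
      rng <- range(history[[cn]], na.rm = TRUE)
      if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
    } else {
      lev <- sort(unique(as.character(history[[cn]])))
      (match(as.character(v), lev) - 1) / max(1, length(lev) - 1)
    }
  })
  if (n == 1L) scaled <- matrix(scaled, nrow = 1, dimnames = list(NULL, cols))
  graphics::plot(NULL, xlim = c(1, length(cols)), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "scaled value",
                 main = if (converged_only) "Converged experiments" else "All experiments")
  graphics::axis(1, at = seq_along(cols), labels = cols, las = 2, cex.axis = 0.7)
  graphics::axis(2)
  if (n == 0L) {
    warning("no converged experiments to draw", call. = FALSE)
  } else {
    shade <- grDevices::gray(0.85 - 0.75 * clamp01(df$merit))
    ord <- order(df$merit)  # draw best last
    for (i in ord)
      graphics::lines(seq_along(cols), scaled[i, ], col = shade[i], lwd = 1.5)
  }
  invisible(list(n_traces = n, columns = cols))
}
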