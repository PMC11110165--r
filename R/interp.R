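# Scattered-data interpolation on the embedding plane: Bowyer-Watson
# Delaunay triangulation, barycentric linear interpolation inside the convex
# hull, nearest-neighbor fill outside. Linear interpolation keeps the
# contour elevations bounded by the input value range and reproduces the
# input values exactly at the data points.

# Circumcircle test: is point p inside the circumcircle of triangle (a,b,c)?
# a, b, c counter-clockwise.
in_circumcircle <- function(ax, ay, bx, by, cx, cy, px, py) {
  ax <- ax - px; ay <- ay - py
  bx <- bx - px; by <- by - py
  cx <- cx - px; cy <- cy - py
  det <- (ax^2 + ay^2) * (bx * cy - cx * by) -
         (bx^2 + by^2) * (ax * cy - cx * ay) +
         (cx^2 + cy^2) * (ax * by - bx * ay)
  det > 1e-12
}

ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)

#' Delaunay triangulation (Bowyer-Watson)
#'
#' @param x,y point coordinates (duplicates are collapsed).
#' @return integer matrix, one triangle per row, 1-based vertex indices into
#'   the input points.
#' @keywords internal
delaunay <- function(x, y) {
  n <- length(x)
  # super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- max(diff(range(x)), diff(range(y)), 1e-9) * 20
  px <- c(x, cx - 2 * r, cx + 2 * r, cx)
  py <- c(y, cy - r, cy - r, cy + 2 * r)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- list(c(s1, s2, s3))
  seen <- cbind(x, y)
  for (i in seq_len(n)) {
    if (i > 1 && any(abs(x[i] - x[seq_len(i - 1)]) < 1e-12 &
                     abs(y[i] - y[seq_len(i - 1)]) < 1e-12)) next  # exact duplicate
    bad <- vapply(tris, function(t) {
      # ensure ccw orientation for the circumcircle test
      a <- t[1]; b <- t[2]; c <- t[3]
      if (ccw(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) { tmp <- b; b <- c; c <- tmp }
      in_circumcircle(px[a], py[a], px[b], py[b], px[c], py[c], px[i], py[i])
    }, logical(1))
    if (!any(bad)) next
    cavity <- tris[bad]
    tris <- tris[!bad]
    edges <- do.call(rbind, lapply(cavity, function(t)
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (e in seq_len(nrow(boundary)))
      tris[[length(tris) + 1L]] <- c(boundary[e, 1], boundary[e, 2], i)
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  out <- do.call(rbind, tris[keep])
  if (is.null(out)) out <- matrix(integer(0), 0, 3)
  out
}

#' Interpolate scattered values at query locations
#'
#' Linear (barycentric) interpolation within the convex hull of the data,
#' nearest-neighbor fill outside. At a data point the data value is
#' reproduced exactly; inside the hull the result is bounded by the range of
#' the vertex values.
#'
#' @param x,y data coordinates.
#' @param values data values (same length).
#' @param xq,yq query coordinates.
#' @return interpolated values at the queries.
#' @export
interp_scattered <- function(x, y, values, xq, yq) {
  if (length(values) != length(x))
    stop_rxnbo("values length must match the number of points", "rxnbo_config_error")
  if (diff(range(x)) < 1e-12 && diff(range(y)) < 1e-12)
    stop_rxnbo("all points are (numerically) identical: cannot interpolate",
               "rxnbo_degenerate_geometry")
  tris <- delaunay(x, y)
  out <- rep(NA_real_, length(xq))
  for (t in seq_len(nrow(tris))) {
    a <- tris[t, 1]; b <- tris[t, 2]; c <- tris[t, 3]
    det <- (y[b] - y[c]) * (x[a] - x[c]) + (x[c] - x[b]) * (y[a] - y[c])
    if (abs(det) < 1e-14) next
    need <- which(is.na(out))
    if (!length(need)) break
    l1 <- ((y[b] - y[c]) * (xq[need] - x[c]) + (x[c] - x[b]) * (yq[need] - y[c])) / det
    l2 <- ((y[c] - y[a]) * (xq[need] - x[c]) + (x[a] - x[c]) * (yq[need] - y[c])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    idx <- need[inside]
    out[idx] <- l1[inside] * values[a] + l2[inside] * values[b] + l3[inside] * values[c]
  }
  # nearest-neighbor fill outside the hull (and for degenerate triangulations)
  miss <- which(is.na(out))
  if (length(miss)) {
    for (i in miss) {
      j <- which.min((x - xq[i])^2 + (y - yq[i])^2)
      out[i] <- values[j]
    }
  }
  out
}
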