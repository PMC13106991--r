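#' Distance from points to a polyline
#'
#' Euclidean distance from one or more points to the nearest point (segment
#' interior or vertex) of a polyline, in the planar metre frame of the
#' landscape. No geodesic correction is applied; at the kilometre scale of a
#' coastal meadow a projected planar frame is assumed throughout.
#'
#' @param point Numeric vector `c(x, y)` or a two-column matrix of points.
#' @param polyline Two-column coordinate matrix with at least 2 rows.
#' @return Numeric vector of distances (metres), one per point.
#' @export
#' @examples
#' point_to_polyline_distance(c(0, 5), rbind(c(0, 0), c(10, 0)))
point_to_polyline_distance <- function(point, polyline) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) {
    stop("polyline must have at least 2 vertices", call. = FALSE)
  }
  if (!all(is.finite(polyline))) {
    stop("polyline coordinates must be finite", call. = FALSE)
  }
  ax <- polyline[-nrow(polyline), 1]; ay <- polyline[-nrow(polyline), 2]
  bx <- polyline[-1, 1]; by <- polyline[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  out <- numeric(nrow(point))
  for (i in seq_len(nrow(point))) {
    px <- point[i, 1]; py <- point[i, 2]
    # Projection parameter clamped to [0, 1]: nearest point on each segment.
    tt <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
    tt <- pmin(1, pmax(0, tt))
    qx <- ax + tt * dx; qy <- ay + tt * dy
    out[i] <- sqrt(min((px - qx)^2 + (py - qy)^2))
  }
  out
}

min_dist_to_multiline <- function(points, lines) {
  d <- vapply(lines, function(l) point_to_polyline_distance(points, l),
              numeric(nrow(points)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  apply(d, 1, min)
}

#' Distance to the nearest lek active in a given year
#'
#' @param point Numeric `c(x, y)` or two-column matrix.
#' @param leks Lek tibble (`lek_id`, `x`, `y`, list-column `years`).
#' @param year Breeding season.
#' @return Numeric vector of distances (m) to the centre of the closest lek
#'   active that year. Ties share the common distance.
#' @export
nearest_lek_distance <- function(point, leks, year) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  active <- vapply(leks$years, function(a) year %in% a, logical(1))
  if (!any(active)) {
    stop("no lek active in year ", year, call. = FALSE)
  }
  lx <- leks$x[active]; ly <- leks$y[active]
  vapply(seq_len(nrow(point)), function(i) {
    sqrt(min((point[i, 1] - lx)^2 + (point[i, 2] - ly)^2))
  }, numeric(1))
}

#' Mean daily nearest-active-nest distance
#'
#' For every day a focal nest is active (lay day to end day, closed
#' interval), the distance to the closest other nest of the same year active
#' that same day is taken; the per-nest covariate is the mean of those daily
#' shortest distances over the days on which at least one neighbour was
#' active. Days without any concurrently active neighbour are dropped from
#' the mean; a nest with no temporal overlap at all gets `NA`.
#'
#' @param nests Nest tibble with `nest_id`, `year`, `x`, `y`, `lay_day`,
#'   `end_day`.
#' @return Numeric vector, one value per row of `nests` (metres or `NA`).
#' @export
mean_daily_nearest_nest_distance <- function(nests) {
  out <- rep(NA_real_, nrow(nests))
  for (yr in unique(nests$year)) {
    idx <- which(nests$year == yr)
    n <- length(idx)
    if (n < 2) next
    xy <- cbind(nests$x[idx], nests$y[idx])
    D <- as.matrix(stats::dist(xy))
    diag(D) <- Inf
    lay <- nests$lay_day[idx]; end <- nests$end_day[idx]
    sums <- numeric(n); cnts <- integer(n)
    for (d in seq(min(lay), max(end))) {
      act <- which(lay <= d & d <= end)
      if (length(act) < 2) next
      sub <- D[act, act, drop = FALSE]
      mins <- apply(sub, 1, min)
      sums[act] <- sums[act] + mins
      cnts[act] <- cnts[act] + 1L
    }
    out[idx] <- ifelse(cnts > 0, sums / cnts, NA_real_)
  }
  out
}

#' Per-nest distance covariates
#'
#' Computes the five distance covariates for each nest: mean daily
#' nearest-active-nest distance, distance to the nearest lek active that
#' year, and nearest-point distances to the shoreline, the meadow edge and
#' the closest path.
#'
#' @param nests Nest tibble (`nest_id`, `year`, `x`, `y`, `lay_day`,
#'   `end_day`).
#' @param landscape A `"ruff_landscape"`.
#' @return The input tibble with columns `dist_nests`, `dist_leks`,
#'   `dist_shore`, `dist_edge`, `dist_path` appended (metres).
#' @export
nest_distances <- function(nests, landscape) {
  stopifnot(inherits(landscape, "ruff_landscape"))
  pts <- cbind(nests$x, nests$y)
  dist_leks <- rep(NA_real_, nrow(nests))
  for (yr in unique(nests$year)) {
    i <- nests$year == yr
    dist_leks[i] <- nearest_lek_distance(pts[i, , drop = FALSE],
                                         landscape$leks, yr)
  }
  nests |>
    dplyr::mutate(
      dist_nests = mean_daily_nearest_nest_distance(nests),
      dist_leks = dist_leks,
      dist_shore = point_to_polyline_distance(pts, landscape$shoreline),
      dist_edge = point_to_polyline_distance(pts, landscape$meadow_edge),
      dist_path = min_dist_to_multiline(pts, landscape$paths)
    )
}

#' Pairwise Pearson correlations between distance predictors
#'
#' Pearson correlation coefficients with two-sided p-values for every pair
#' of predictor columns, on pairwise-complete observations, to flag spatial
#' redundancy among the distance covariates before modelling.
#'
#' @param distances Tibble of per-nest covariates.
#' @param cols Columns to correlate (default: the five distance covariates
#'   present in `distances`).
#' @return Object of class `"dsr_cormat"`: list with symmetric matrices `r`,
#'   `p` and `n` (complete pairs). A column with zero variance yields `NA`
#'   correlations with a warning. Use [generics::tidy()] for a long tibble.
#' @export
#' @examples
#' predictor_correlation_matrix(
#'   tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' )$r
predictor_correlation_matrix <- function(distances, cols = NULL) {
  if (is.null(cols)) {
    cols <- intersect(
      c("dist_nests", "dist_leks", "dist_shore", "dist_edge", "dist_path"),
      names(distances)
    )
    if (length(cols) == 0) cols <- names(distances)[vapply(distances, is.numeric, logical(1))]
  }
  k <- length(cols)
  stopifnot(k >= 2)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      x <- distances[[cols[i]]]; y <- distances[[cols[j]]]
      ok <- stats::complete.cases(x, y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        warning("fewer than 3 complete pairs for ", cols[i], " vs ", cols[j])
        next
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("zero variance in ", cols[i], " or ", cols[j],
                "; correlation undefined")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- vapply(cols, function(cl) sum(!is.na(distances[[cl]])), numeric(1))
  structure(list(r = r, p = p, n = n), class = "dsr_cormat")
}

#' @export
print.dsr_cormat <- function(x, digits = 2, ...) {
  cat("<dsr_cormat> Pearson correlations (lower triangle: p-values)\n")
  m <- round(x$r, digits)
  m[lower.tri(m)] <- round(x$p[lower.tri(x$p)], 3)
  print(m)
  invisible(x)
}

#' @export
tidy.dsr_cormat <- function(x, ...) {
  cols <- rownames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = cols[pairs[, 1]], var2 = cols[pairs[, 2]],
    r = x$r[pairs], p.value = x$p[pairs], n = x$n[pairs]
  )
}
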