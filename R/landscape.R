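#' Generate the meadow landscape
#'
#' Lays out the spatial features of the study site in a planar metric frame
#' (metres): a wiggly shoreline along the top of the meadow
#' (`y = meadow_height`), the meadow edge (outer fence) along the bottom
#' (`y = 0`), a set of paths crossing the meadow, and lek points inside the
#' nesting band. Shoreline and edge therefore lie on opposite sides of the
#' meadow, as on a coastal meadow strip.
#'
#' @param config A [scenario_config()].
#' @return A list of class `"ruff_landscape"` with elements `shoreline`
#'   (two-column coordinate matrix), `meadow_edge` (matrix), `paths` (list
#'   of matrices), `leks` (tibble with `lek_id`, `x`, `y` and a list-column
#'   `years` of active years) and `extent`.
#' @export
#' @examples
#' land <- generate_landscape(scenario_config(rng_seed = 3))
#' land
generate_landscape <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$meadow_width <= 0 || config$meadow_height <= 0) {
    stop("degenerate meadow extent: width and height must be positive",
         call. = FALSE)
  }
  W <- config$meadow_width
  H <- config$meadow_height
  with_seed(config$rng_seed + 1L, {
    # Shoreline: gentle large-scale curve plus small noise, overshooting the
    # meadow ends so every nest has a nearest shoreline point inboard.
    xs <- seq(-100, W + 100, length.out = 60)
    shoreline <- cbind(
      x = xs,
      y = H - 40 * (1 + sin(xs / W * 2 * pi + stats::runif(1, 0, pi))) / 2 -
        stats::rnorm(length(xs), 0, 6)
    )
    edge <- cbind(
      x = xs,
      y = 30 * (1 + sin(xs / W * 1.5 * pi + stats::runif(1, 0, pi))) / 2 +
        abs(stats::rnorm(length(xs), 0, 5))
    )
    # Paths run roughly top-to-bottom at regular spacing with jittered bends.
    spacing <- W / config$n_paths
    paths <- lapply(seq_len(config$n_paths), function(k) {
      x0 <- (k - 0.5) * spacing + stats::runif(1, -0.15, 0.15) * spacing
      yy <- seq(0, H, length.out = 6)
      cbind(x = x0 + cumsum(c(0, stats::rnorm(5, 0, spacing * 0.06))), y = yy)
    })
    # Leks: spaced points inside the nesting band, concentrated in part of
    # the meadow so lek distances span a wide range.
    leks <- tibble::tibble(lek_id = integer(), x = numeric(), y = numeric(),
                           years = list())
    if (config$n_leks > 0) {
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(pts) < config$n_leks && tries < 5000) {
        cand <- c(stats::runif(1, config$lek_x_range[1], config$lek_x_range[2]),
                  stats::runif(1, config$nesting_band[1], config$nesting_band[2]))
        if (nrow(pts) == 0 ||
            min(sqrt(colSums((t(pts) - cand)^2))) > 120) {
          pts <- rbind(pts, cand)
        }
        tries <- tries + 1
      }
      active <- lapply(seq_len(nrow(pts)), function(i) {
        yrs <- config$years[stats::runif(config$n_years) < 0.8]
        if (length(yrs) == 0) yrs <- sample(config$years, 1)
        sort(yrs)
      })
      # Guarantee at least one active lek every year.
      for (yr in config$years) {
        if (!any(vapply(active, function(a) yr %in% a, logical(1)))) {
          i <- sample(length(active), 1)
          active[[i]] <- sort(c(active[[i]], yr))
        }
      }
      leks <- tibble::tibble(
        lek_id = seq_len(nrow(pts)), x = unname(pts[, 1]),
        y = unname(pts[, 2]), years = active
      )
    }
    structure(
      list(
        shoreline = shoreline, meadow_edge = edge, paths = paths, leks = leks,
        extent = c(xmin = 0, xmax = W, ymin = 0, ymax = H)
      ),
      class = "ruff_landscape"
    )
  })
}

#' @export
print.ruff_landscape <- function(x, ...) {
  cat("<ruff_landscape>\n")
  cat(sprintf("  shoreline: %d vertices; meadow edge: %d vertices\n",
              nrow(x$shoreline), nrow(x$meadow_edge)))
  cat(sprintf("  %d path(s), %d lek(s); extent %g x %g m\n",
              length(x$paths), nrow(x$leks),
              x$extent["xmax"] - x$extent["xmin"],
              x$extent["ymax"] - x$extent["ymin"]))
  invisible(x)
}

coords_to_list <- function(m) {
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write and read a landscape as GeoJSON
#'
#' Features carry a `role` property (`"shoreline"`, `"edge"`, `"path"` or
#' `"lek"`); lek features additionally carry `lek_id` and their active
#' `years`. Coordinates are planar metres, recorded in the file as-is.
#'
#' @param landscape A `"ruff_landscape"`.
#' @param path Output file path.
#' @return `write_landscape_geojson()` returns `path` invisibly;
#'   `read_landscape_geojson()` returns a `"ruff_landscape"`.
#' @export
write_landscape_geojson <- function(landscape, path) {
  stopifnot(inherits(landscape, "ruff_landscape"))
  feat <- function(geom_type, coords, props) {
    list(type = "Feature", properties = props,
         geometry = list(type = geom_type, coordinates = coords))
  }
  features <- c(
    list(
      feat("LineString", coords_to_list(landscape$shoreline),
           list(role = "shoreline")),
      feat("LineString", coords_to_list(landscape$meadow_edge),
           list(role = "edge"))
    ),
    lapply(landscape$paths, function(p) {
      feat("LineString", coords_to_list(p), list(role = "path"))
    }),
    if (nrow(landscape$leks) > 0) {
      lapply(seq_len(nrow(landscape$leks)), function(i) {
        feat("Point", c(landscape$leks$x[i], landscape$leks$y[i]),
             list(role = "lek", lek_id = landscape$leks$lek_id[i],
                  years = landscape$leks$years[[i]]))
      })
    }
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_landscape_geojson
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) unlist(p)))
    colnames(m) <- c("x", "y")
    m
  }
  shoreline <- NULL; edge <- NULL; paths <- list()
  lek_rows <- list()
  for (f in gj$features) {
    role <- f$properties$role
    if (identical(role, "shoreline")) {
      shoreline <- mat(f$geometry$coordinates)
    } else if (identical(role, "edge")) {
      edge <- mat(f$geometry$coordinates)
    } else if (identical(role, "path")) {
      paths <- c(paths, list(mat(f$geometry$coordinates)))
    } else if (identical(role, "lek")) {
      co <- unlist(f$geometry$coordinates)
      lek_rows <- c(lek_rows, list(tibble::tibble(
        lek_id = as.integer(f$properties$lek_id),
        x = co[1], y = co[2],
        years = list(as.integer(unlist(f$properties$years)))
      )))
    }
  }
  if (is.null(shoreline) || is.null(edge)) {
    stop("GeoJSON is missing a shoreline or edge feature", call. = FALSE)
  }
  leks <- if (length(lek_rows) > 0) {
    dplyr::bind_rows(lek_rows)
  } else {
    tibble::tibble(lek_id = integer(), x = numeric(), y = numeric(),
                   years = list())
  }
  allx <- c(shoreline[, 1], edge[, 1])
  ally <- c(shoreline[, 2], edge[, 2])
  structure(
    list(shoreline = shoreline, meadow_edge = edge, paths = paths,
         leks = leks,
         extent = c(xmin = min(allx), xmax = max(allx),
                    ymin = min(0, ally), ymax = max(ally))),
    class = "ruff_landscape"
  )
}
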