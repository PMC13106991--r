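#' Nest fate summary per year and pooled
#'
#' Counts and percentages of hatched nests, and of failure causes among
#' failed nests, per year and pooled, under either variant's fate
#' attribution. For the `natural_only` variant flood-protected nests are
#' attributed to flooding on their intervention day (the clutch was
#' collected because the water would have reached it) and
#' trampling-protected nests are set aside as censored; nests with fully
#' unknown or "escaped" fates are excluded from the denominators.
#' Percentages are rounded to one decimal place.
#'
#' @param nests Nest tibble with fates.
#' @param variant `"all_nests"` or `"natural_only"`.
#' @return Tibble with one row per year plus a pooled `"all"` row: `n`
#'   (fate-known nests), `n_hatched`, `pct_hatched`, `n_failed` and
#'   `pct_predated`, `pct_flooded`, `pct_trampled`, `pct_abandoned`,
#'   `pct_unknown_cause` (shares of failed nests; `NA` when no nest
#'   failed).
#' @export
fate_summary_table <- function(nests, variant = "all_nests") {
  variant <- check_variant(variant)
  x <- nests
  if (variant == "natural_only") {
    prot <- x$protected_cause %||% rep("none", nrow(x))
    prot[is.na(prot)] <- "none"
    flood_prot <- prot == "flood"
    x$fate[flood_prot] <- "flooded"
    x$end_day[flood_prot] <- x$intervention_day[flood_prot]
    x <- x[prot != "trampling", , drop = FALSE]
  }
  x <- x[!(x$fate %in% c("unknown", "escaped")), , drop = FALSE]
  summarise_block <- function(d, label) {
    n <- nrow(d)
    n_hatched <- sum(d$fate == "hatched")
    n_failed <- sum(d$fate %in% FATES_FAILED)
    pct <- function(k) {
      if (n_failed == 0) NA_real_ else round(100 * k / n_failed, 1)
    }
    tibble::tibble(
      year = label, n = n, n_hatched = n_hatched,
      pct_hatched = if (n == 0) NA_real_ else round(100 * n_hatched / n, 1),
      n_failed = n_failed,
      pct_predated = pct(sum(d$fate == "predated")),
      pct_flooded = pct(sum(d$fate == "flooded")),
      pct_trampled = pct(sum(d$fate == "trampled")),
      pct_abandoned = pct(sum(d$fate == "abandoned")),
      pct_unknown_cause = pct(sum(d$fate == "unknown_dead"))
    )
  }
  per_year <- lapply(sort(unique(x$year)), function(yr) {
    summarise_block(x[x$year == yr, , drop = FALSE], as.character(yr))
  })
  dplyr::bind_rows(c(per_year, list(summarise_block(x, "all"))))
}

#' Outcomes of protected nests
#'
#' Breakdown of realized fates for nests whose clutches were swapped for
#' dummy eggs, by protection cause and by whether the protection lasted
#' long enough to count as artificial incubation.
#'
#' @param nests Nest tibble.
#' @return Tibble `protected_cause`, `artificially_incubated`, `fate`, `n`.
#' @export
protected_outcome_table <- function(nests) {
  prot <- nests$protected_cause %||% rep("none", nrow(nests))
  prot[is.na(prot)] <- "none"
  x <- nests[prot != "none", , drop = FALSE]
  x |>
    dplyr::count(.data$protected_cause, .data$artificially_incubated,
                 .data$fate, name = "n") |>
    dplyr::arrange(.data$protected_cause,
                   dplyr::desc(.data$artificially_incubated), .data$fate)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, SD, central 95% and 80% credible intervals
#' and the clear-effect flag (95% CrI excluding zero). Year rows summarise
#' the composite year contribution `sigma_year * u_year`.
#'
#' @param draws A `"dsr_fit"` or a draws matrix/array with named columns.
#' @return Tibble `term`, `mean`, `sd`, `cri_lower`, `cri_upper`,
#'   `cri80_lower`, `cri80_upper`, `clear`.
#' @export
posterior_summary_table <- function(draws) {
  m <- draws_matrix(draws)
  q <- apply(m, 2, stats::quantile,
             probs = c(0.025, 0.975, 0.10, 0.90), names = FALSE)
  tibble::tibble(
    term = colnames(m),
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2, stats::sd)),
    cri_lower = unname(q[1, ]), cri_upper = unname(q[2, ]),
    cri80_lower = unname(q[3, ]), cri80_upper = unname(q[4, ]),
    clear = unname(sign(q[1, ]) == sign(q[2, ]) & q[1, ] != 0)
  )
}

curve_raw_col <- c(
  Nests = "dist_nests", Leks = "dist_leks", LayDate = "lay_day",
  Path = "dist_path", Edges = "dist_edge", Shore = "dist_shore"
)
curve_quad_term <- c(Nests = "Q.Nests", Leks = "Q.Leks")

#' Posterior daily survival prediction curve
#'
#' Daily survival probability along a grid of one covariate with all other
#' predictors held at their (scaled) mean of 0 and the year effect at 0.
#' Raw grid values are mapped to the model scale through the stored
#' year-wise scaling, averaged over years; nest age uses its fixed window
#' scaling. For covariates with a quadratic term both terms move along the
#' grid.
#'
#' @param fit A `"dsr_fit"`.
#' @param covariate One of `"Nests"`, `"Leks"`, `"LayDate"`, `"NestAge"`,
#'   `"Path"`, `"Edges"`, `"Shore"`.
#' @param grid Raw-scale grid values; default 100 points over the observed
#'   range (1..26 for `NestAge`). Values outside the observed range warn
#'   but are computed.
#' @return Tibble of class `"dsr_curve"`: `covariate`, `x` (raw), `scaled`,
#'   `mean`, `lower95`, `upper95`, `lower80`, `upper80`.
#' @export
dsr_prediction_curve <- function(fit, covariate, grid = NULL) {
  stopifnot(inherits(fit, "dsr_fit"))
  covariate <- rlang::arg_match0(
    covariate, c("Nests", "Leks", "LayDate", "NestAge", "Path", "Edges",
                 "Shore")
  )
  if (covariate == "NestAge") {
    if (is.null(grid)) grid <- 1:26
    z <- age_scale(grid)
    obs_range <- c(1, 26)
  } else {
    raw_col <- curve_raw_col[[covariate]]
    sc <- fit$scaling[fit$scaling$covariate == raw_col, , drop = FALSE]
    if (nrow(sc) == 0) {
      stop("no stored scaling for covariate ", covariate, call. = FALSE)
    }
    m <- mean(sc$mean, na.rm = TRUE)
    s <- mean(sc$sd, na.rm = TRUE)
    obs_range <- fit$raw_ranges[[covariate]] %||% c(-Inf, Inf)
    if (is.null(grid)) {
      grid <- seq(obs_range[1], obs_range[2], length.out = 100)
    }
    z <- (grid - m) / s
  }
  if (any(grid < obs_range[1] | grid > obs_range[2])) {
    warning("grid extends outside the observed covariate range")
  }
  dm <- draws_matrix(fit)
  eta <- outer(dm[, "Intercept"], rep(1, length(z)))
  if (covariate %in% colnames(dm)) {
    eta <- eta + dm[, covariate] %o% z
  }
  quad <- curve_quad_term[covariate]
  if (!is.na(quad) && quad %in% colnames(dm)) {
    eta <- eta + dm[, quad] %o% (z^2)
  }
  S <- inv_logit(eta)
  out <- tibble::tibble(
    covariate = covariate, x = grid, scaled = z,
    mean = colMeans(S),
    lower95 = apply(S, 2, stats::quantile, 0.025, names = FALSE),
    upper95 = apply(S, 2, stats::quantile, 0.975, names = FALSE),
    lower80 = apply(S, 2, stats::quantile, 0.10, names = FALSE),
    upper80 = apply(S, 2, stats::quantile, 0.90, names = FALSE)
  )
  class(out) <- c("dsr_curve", class(out))
  out
}

#' Cumulative hatch probability over the 26-day window
#'
#' Product of daily survival probabilities over the 26 transitions from
#' laying to hatching. A scalar is treated as a constant daily rate.
#'
#' @param daily_s Daily survival probabilities: a scalar or a vector of
#'   length 26.
#' @return Probability that a nest survives the whole window.
#' @export
#' @examples
#' cumulative_hatch_probability(0.98)  # 0.98^26
cumulative_hatch_probability <- function(daily_s) {
  stopifnot(all(daily_s >= 0 & daily_s <= 1))
  if (length(daily_s) == 1) {
    daily_s^26
  } else {
    stopifnot(length(daily_s) == 26)
    prod(daily_s)
  }
}

#' @export
autoplot.dsr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower80, ymax = .data$upper80),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower95), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper95), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.9) +
    ggplot2::labs(
      x = object$covariate[1], y = "Daily nest survival probability"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dsr_fit <- function(object, ...) {
  s <- posterior_summary_table(object)
  s <- s[s$term %in% COEF_NAMES & s$term != "Intercept", , drop = FALSE]
  s$term <- factor(s$term, levels = rev(s$term))
  ggplot2::ggplot(s, ggplot2::aes(y = .data$term, colour = .data$clear)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cri_lower, xend = .data$cri_upper,
                   yend = .data$term), linewidth = 0.4
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cri80_lower, xend = .data$cri80_upper,
                   yend = .data$term), linewidth = 1.4
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#4b0082", `FALSE` = "grey55"),
      name = "95% CrI excludes 0"
    ) +
    ggplot2::labs(x = "Posterior coefficient (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write posterior draws and summaries to disk
#'
#' Draws go to a long CSV (`chain`, `iteration`, one column per parameter),
#' the summary table and convergence report to CSVs alongside.
#'
#' @param fit A `"dsr_fit"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_csv <- function(fit, dir) {
  stopifnot(inherits(fit, "dsr_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(fit$draws)
  long <- tidyr::expand_grid(chain = seq_len(d[2]), iteration = seq_len(d[1]))
  # array order is iteration-fastest within chain, matching `long`
  for (k in seq_len(d[3])) {
    long[[fit$par_names[k]]] <- as.numeric(fit$draws[, , k])
  }
  readr::write_csv(long, file.path(dir, "draws.csv"))
  readr::write_csv(posterior_summary_table(fit),
                   file.path(dir, "summary.csv"))
  readr::write_csv(
    tibble::tibble(parameter = names(fit$rhat), rhat = unname(fit$rhat)),
    file.path(dir, "convergence.csv")
  )
  invisible(dir)
}
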