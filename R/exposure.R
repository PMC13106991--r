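#' Estimate a nest's timeline from its hatching day and clutch size
#'
#' Back-dates the nest initiation from the (exact or expected) hatching day
#' using a 21-day incubation period and a laying interval of 1.25 days per
#' egg. Incubation starts when the clutch is complete, so the laying
#' interval spans `clutch_size - 1` inter-egg gaps; the lay day is rounded
#' to the nearest whole day.
#'
#' @param hatch_day Day-of-season of hatching (or its flotation-based
#'   estimate); vectorised.
#' @param clutch_size Number of eggs (>= 1); vectorised.
#' @return Tibble with `lay_day` and `incubation_onset`.
#' @export
#' @examples
#' estimate_timeline(100, 4) # incubation onset 79, lay day 75
estimate_timeline <- function(hatch_day, clutch_size) {
  stopifnot(all(clutch_size >= 1))
  incubation_onset <- hatch_day - 21
  lay_day <- round(incubation_onset - 1.25 * (clutch_size - 1))
  if (any(lay_day < 0)) {
    stop("estimated lay day is negative; season frame too small",
         call. = FALSE)
  }
  tibble::tibble(lay_day = as.integer(lay_day),
                 incubation_onset = as.integer(incubation_onset))
}

#' Cap nest activity at 26 days after laying
#'
#' Nests are modelled only for the 26 days following egg laying; longer
#' observed activity (typical of manipulated nests) is truncated. A record
#' whose event fell beyond the cap keeps its fate label but is marked
#' `capped`, and encodings treat it as having survived the modelled window.
#'
#' @param nests Nest tibble with `lay_day`, `end_day`, `fate`.
#' @return The tibble with `end_day` capped at `lay_day + 26` and a logical
#'   `capped` column.
#' @export
cap_activity <- function(nests) {
  stopifnot(all(nests$end_day >= nests$lay_day, na.rm = TRUE))
  nests |>
    dplyr::mutate(
      capped = .data$end_day > .data$lay_day + 26L,
      end_day = pmin(.data$end_day, .data$lay_day + 26L)
    )
}

scenario_failure_fates <- function(scenario) {
  switch(scenario,
    overall = c("predated", "flooded", "trampled", "abandoned", "unknown_dead"),
    no_predation = c("flooded", "trampled", "abandoned"),
    predation = "predated"
  )
}

#' Encode nest records as daily survival histories
#'
#' Turns capped nest records into Bernoulli exposure-day histories
#' `y_1, ..., y_T` for a mortality scenario and dataset variant. Day `t`
#' indexes transitions after the lay day (`t = 0` is the lay day, alive by
#' definition; `T <= 26`).
#'
#' The `natural_only` variant first discards post-intervention information
#' for protected nests: flood-protected clutches (collected because the
#' water would have reached them) are recorded as failed due to flooding on
#' the intervention day, while trampling-protected clutches are censored on
#' the intervention day, alive at their last observation. The `all_nests`
#' variant keeps realized fates.
#'
#' Scenario rules then assign failures and censorings:
#' * `overall`: predated, flooded, trampled, abandoned and unknown-dead
#'   records are failures (`y_T = 0` on the failure day);
#' * `no_predation`: predated nests are censored; flooded, trampled and
#'   abandoned are failures;
#' * `predation`: only predated nests are failures; other deaths are
#'   censored.
#' Unknown and escaped fates are censored in every scenario, and
#' unknown-dead records are failures only in `overall` (the cause cannot be
#' attributed to either side of the split). A nest censored at a failure
#' found on day `d` contributes survived transitions up to day `d - 1`;
#' hatched nests and capped records contribute an all-ones history.
#'
#' @param nests Nest tibble (capped via [cap_activity()]; applied
#'   automatically if the `capped` column is missing).
#' @param scenario `"overall"`, `"no_predation"` or `"predation"`.
#' @param variant `"all_nests"` or `"natural_only"`.
#' @return Long tibble with columns `nest_id`, `year`, `scenario`,
#'   `variant`, `t` (1..T) and `y`; the per-nest terminal status is attached
#'   as attribute `"terminals"` (tibble `nest_id`, `terminal`, `T`).
#' @export
encode_histories <- function(nests, scenario = "overall",
                             variant = "all_nests") {
  scenario <- check_scenario(scenario)
  variant <- check_variant(variant)
  if (!"capped" %in% names(nests)) nests <- cap_activity(nests)
  bad <- setdiff(unique(nests$fate), FATES_ALL)
  if (length(bad) > 0) {
    stop("unknown fate label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prot <- nests$protected_cause %||% rep("none", nrow(nests))
  prot[is.na(prot)] <- "none"
  iv <- nests$intervention_day %||% rep(NA_integer_, nrow(nests))
  has_iv <- prot != "none" & !is.na(iv)
  if (any(has_iv & (iv < nests$lay_day | iv > nests$lay_day + 26L))) {
    off <- which(has_iv & (iv < nests$lay_day | iv > nests$lay_day + 26L))[1]
    stop("intervention day outside the active window for nest ",
         nests$nest_id[off], call. = FALSE)
  }

  lay <- nests$lay_day
  fate <- nests$fate
  exposure <- nests$end_day - lay
  failure_fates <- scenario_failure_fates(scenario)

  # Terminal status and history length per nest.
  n <- nrow(nests)
  T_len <- integer(n)
  yT <- integer(n)  # value of the last transition (1 = alive, 0 = failed)
  terminal <- character(n)
  for (i in seq_len(n)) {
    fate_i <- fate[i]
    exp_i <- exposure[i]
    capped_i <- isTRUE(nests$capped[i])
    if (variant == "natural_only" && prot[i] == "flood") {
      # Natural clutch collected on the surge day: treated as flooded on
      # the intervention day, then classified by the scenario rules
      # (failure in overall / no-predation, censored in predation).
      fate_i <- "flooded"
      exp_i <- iv[i] - lay[i]
      capped_i <- FALSE
    }
    if (variant == "natural_only" && prot[i] == "trampling") {
      # Censored on the intervention day, alive at the last observation.
      T_len[i] <- iv[i] - lay[i]; yT[i] <- 1L; terminal[i] <- "censored"
      next
    }
    if (capped_i || fate_i == "hatched") {
      T_len[i] <- exp_i; yT[i] <- 1L; terminal[i] <- "survived_window"
    } else if (fate_i %in% failure_fates) {
      T_len[i] <- exp_i; yT[i] <- 0L; terminal[i] <- "failed"
    } else {
      # Censored: last known-active day is the day before the event was
      # found (for unknown/escaped and out-of-scenario deaths).
      T_len[i] <- exp_i - 1L; yT[i] <- 1L; terminal[i] <- "censored"
    }
  }

  keep <- T_len > 0L
  hist <- tibble::tibble(
    nest_id = rep(nests$nest_id[keep], T_len[keep]),
    year = rep(nests$year[keep], T_len[keep]),
    scenario = scenario, variant = variant,
    t = unlist(lapply(T_len[keep], seq_len), use.names = FALSE),
    y = 1L
  )
  last <- cumsum(T_len[keep])
  hist$y[last] <- yT[keep]
  attr(hist, "terminals") <- tibble::tibble(
    nest_id = nests$nest_id, terminal = terminal, T = T_len
  )
  hist
}

#' Centre and scale covariates within year
#'
#' Each listed column is centred on its year mean and divided by its year
#' sample standard deviation, independently per year. A column with zero
#' within-year variance is set to 0 for that year with a warning.
#'
#' @param tbl Tibble with a `year` column.
#' @param cols Character vector of columns to scale; defaults to all numeric
#'   columns except `year`.
#' @return `tbl` with the columns replaced by their scaled values and a
#'   `"scaling"` attribute (tibble of `year`, `covariate`, `mean`, `sd`).
#' @export
#' @examples
#' scale_covariates_within_year(
#'   tibble::tibble(year = c(1, 1, 1), x = c(0, 10, 20))
#' )$x
scale_covariates_within_year <- function(tbl, cols = NULL) {
  stopifnot("year" %in% names(tbl))
  if (is.null(cols)) {
    cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], "year")
  }
  scaling <- list()
  for (cl in cols) {
    for (yr in unique(tbl$year)) {
      i <- tbl$year == yr
      v <- tbl[[cl]][i]
      m <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        warning("zero within-year variance for ", cl, " in year ", yr,
                "; scaled values set to 0")
        tbl[[cl]][i] <- 0
        s <- NA_real_
      } else {
        tbl[[cl]][i] <- (v - m) / s
      }
      scaling[[length(scaling) + 1L]] <-
        tibble::tibble(year = yr, covariate = cl, mean = m, sd = s)
    }
  }
  attr(tbl, "scaling") <- dplyr::bind_rows(scaling)
  tbl
}

#' Build the model covariate table from raw distances
#'
#' Scales the five distance covariates and the lay date within year and
#' derives the model's named covariates: `Nests`, `Q.Nests` (square of the
#' scaled linear term), `Leks`, `Q.Leks`, `LayDate`, `Path`, `Edges`,
#' `Shore`. Raw distance columns are kept alongside. A nest with no
#' concurrently active neighbour has an undefined nearest-nest distance; its
#' scaled value is set to 0 (the year mean).
#'
#' @param distances Per-nest tibble from [nest_distances()] with `lay_day`.
#' @return The tibble with model covariate columns appended and the
#'   `"scaling"` attribute of [scale_covariates_within_year()].
#' @export
dsr_covariates <- function(distances) {
  need <- c("dist_nests", "dist_leks", "dist_shore", "dist_edge",
            "dist_path", "lay_day", "year")
  miss <- setdiff(need, names(distances))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- distances
  sc <- scale_covariates_within_year(
    distances,
    cols = c("dist_nests", "dist_leks", "dist_shore", "dist_edge",
             "dist_path", "lay_day")
  )
  out <- raw
  out$Nests <- ifelse(is.na(sc$dist_nests), 0, sc$dist_nests)
  out$Q.Nests <- out$Nests^2
  out$Leks <- sc$dist_leks
  out$Q.Leks <- out$Leks^2
  out$LayDate <- sc$lay_day
  out$Path <- sc$dist_path
  out$Edges <- sc$dist_edge
  out$Shore <- sc$dist_shore
  attr(out, "scaling") <- attr(sc, "scaling")
  out
}

#' Nest-day design matrix for the survival model
#'
#' Expands per-nest covariates to one row per possible transition day
#' (`t = 1..26`) with the scaled nest-age covariate and, for the
#' `all_nests` variant, the artificial-incubation indicator. Joined with an
#' encoded history this gives the model's data.
#'
#' @param covariates Output of [dsr_covariates()] (must include
#'   `artificially_incubated` for the `all_nests` variant).
#' @param variant `"all_nests"` (includes `Incubation`) or `"natural_only"`
#'   (drops it: post-intervention data are excluded there, so the indicator
#'   has nothing to explain).
#' @return Long tibble keyed by `nest_id`, `t` with one column per model
#'   coefficient; the scaling attribute is carried over.
#' @export
dsr_design <- function(covariates, variant = "all_nests") {
  variant <- check_variant(variant)
  static_cols <- c("Nests", "Q.Nests", "Leks", "Q.Leks", "LayDate",
                   "Path", "Edges", "Shore")
  stopifnot(all(static_cols %in% names(covariates)))
  d <- tidyr::expand_grid(
    covariates[, c("nest_id", "year", static_cols,
                   intersect("artificially_incubated", names(covariates)))],
    t = 1:26
  )
  d$Intercept <- 1
  d$NestAge <- age_scale(d$t)
  if (variant == "all_nests") {
    inc <- d$artificially_incubated %||% rep(FALSE, nrow(d))
    inc[is.na(inc)] <- FALSE
    d$Incubation <- as.numeric(inc)
  }
  d$artificially_incubated <- NULL
  out <- d[, c("nest_id", "year", "t", coef_names_for_variant(variant))]
  attr(out, "scaling") <- attr(covariates, "scaling")
  attr(out, "raw_ranges") <- covariate_raw_ranges(covariates)
  out
}

# Observed raw ranges per covariate, used by prediction curves to warn on
# extrapolation.
covariate_raw_ranges <- function(covariates) {
  cols <- c(Nests = "dist_nests", Leks = "dist_leks", LayDate = "lay_day",
            Path = "dist_path", Edges = "dist_edge", Shore = "dist_shore")
  present <- cols[cols %in% names(covariates)]
  purrr::imap(as.list(present), function(cl, nm) {
    range(covariates[[cl]], na.rm = TRUE)
  })
}
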