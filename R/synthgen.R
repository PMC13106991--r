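#' Generate nest locations, lay dates and clutch sizes
#'
#' Places `nests_per_year` nests per season inside the nesting band of the
#' meadow using sequential inhibition: candidate locations are uniform over
#' the band and rejected if they fall within `min_nest_spacing` metres of an
#' already placed same-year nest. Most nests scatter around cluster centres
#' displaced from the year's active leks, the rest are uniform; at the
#' default density this yields mean nearest-nest distances of roughly
#' 120 m. Lay days fall in `[0, season_length - 27]` so each nest can
#' complete its 26-day window; lek-clustered nests lay in loose synchrony
#' around a lek-specific base date, the rest uniformly over the window.
#' Clutch sizes are 4 with probability `clutch_p4`, otherwise 3. No fates
#' are assigned.
#'
#' @param config A [scenario_config()].
#' @param landscape A `"ruff_landscape"` from [generate_landscape()].
#' @return Tibble with `nest_id`, `year`, `x`, `y`, `lay_day`, `end_day`
#'   (`NA`), `fate` (`NA`), `clutch_size`, `protected_cause` (`"none"`),
#'   `intervention_day` (`NA`), `artificially_incubated` (`FALSE`).
#' @export
generate_nests <- function(config, landscape) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(landscape, "ruff_landscape"))
  with_seed(config$rng_seed + 2L, {
    rows <- purrr::map2(config$years, config$nests_per_year, function(yr, n) {
      if (n == 0) {
        return(tibble::tibble(
          nest_id = character(), year = integer(), x = numeric(),
          y = numeric(), lay_day = integer()
        ))
      }
      lk <- landscape$leks
      lk_active <- if (nrow(lk) > 0) {
        which(vapply(lk$years, function(a) yr %in% a, logical(1)))
      } else {
        integer(0)
      }
      span <- config$season_length - 27L
      # Lek clusters lay in loose synchrony: each active lek gets a base
      # lay date for the season, cluster members scatter around it. The
      # cluster centre sits near, not on, the lek (females nest some way
      # off the display site).
      lek_base <- if (length(lk_active) > 0) {
        stats::setNames(sample(0:span, length(lk_active), replace = TRUE),
                        lk_active)
      }
      ctr_x <- lk$x[lk_active] +
        stats::rnorm(length(lk_active), 0, config$cluster_offset_sd)
      ctr_y <- pmin(pmax(
        lk$y[lk_active] +
          stats::rnorm(length(lk_active), 0, config$cluster_offset_sd / 2),
        config$nesting_band[1]), config$nesting_band[2])
      names(ctr_x) <- names(ctr_y) <- lk_active
      xs <- numeric(0); ys <- numeric(0); lays <- integer(0)
      tries <- 0; consec_rej <- 0
      while (length(xs) < n && tries < 2000 * n) {
        # when lek clusters saturate against the inhibition radius, fall
        # back to uniform proposals so placement always completes
        clustered <- consec_rej < 100 && length(lk_active) > 0 &&
          stats::runif(1) < config$cluster_weight
        if (clustered) {
          # lek-clustered placement: nests aggregate around display sites
          j <- lk_active[sample.int(length(lk_active), 1)]
          cx <- stats::rnorm(1, ctr_x[[as.character(j)]], config$cluster_sd)
          cy <- stats::rnorm(1, ctr_y[[as.character(j)]], config$cluster_sd)
          ld <- min(max(lek_base[[as.character(j)]] +
                          as.integer(round(stats::rnorm(1, 0, 3))), 0L), span)
        } else {
          cx <- stats::runif(1, 0, config$meadow_width)
          cy <- stats::runif(1, config$nesting_band[1], config$nesting_band[2])
          ld <- sample(0:span, 1)
        }
        ok_pos <- cx >= 0 && cx <= config$meadow_width &&
          cy >= config$nesting_band[1] && cy <= config$nesting_band[2]
        if (ok_pos &&
            (length(xs) == 0 ||
               min((xs - cx)^2 + (ys - cy)^2) > config$min_nest_spacing^2)) {
          xs <- c(xs, cx); ys <- c(ys, cy); lays <- c(lays, as.integer(ld))
          consec_rej <- 0
        } else {
          consec_rej <- consec_rej + 1
        }
        tries <- tries + 1
      }
      if (length(xs) < n) {
        stop("could not place ", n, " nests with spacing ",
             config$min_nest_spacing, " m in year ", yr, call. = FALSE)
      }
      tibble::tibble(
        nest_id = sprintf("%d_%03d", yr, seq_len(n)),
        year = as.integer(yr), x = xs, y = ys, lay_day = lays
      )
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(
        end_day = NA_integer_, fate = NA_character_,
        clutch_size = 3L + stats::rbinom(dplyr::n(), 1L, config$clutch_p4),
        protected_cause = "none", intervention_day = NA_integer_,
        artificially_incubated = FALSE
      )
  })
}

# Static scaled covariates used by the generative walk. Nearest-nest
# distances are computed over the potential 26-day activity windows (fates
# are not known yet when the process generates them).
simulation_covariates <- function(nests, landscape) {
  tmp <- nests
  tmp$end_day <- tmp$lay_day + 26L
  dists <- nest_distances(tmp, landscape)
  dsr_covariates(dists)
}

# Linear predictor pieces that do not change over days.
static_eta <- function(scaled, beta) {
  beta["Intercept"] +
    beta["Nests"] * scaled$Nests + beta["Q.Nests"] * scaled$Q.Nests +
    beta["Leks"] * scaled$Leks + beta["Q.Leks"] * scaled$Q.Leks +
    beta["LayDate"] * scaled$LayDate +
    beta["Path"] * scaled$Path + beta["Edges"] * scaled$Edges +
    beta["Shore"] * scaled$Shore
}

in_zone <- function(x, y, zone) {
  x >= zone["xmin"] & x <= zone["xmax"] & y >= zone["ymin"] & y <= zone["ymax"]
}

flood_duration_for_year <- function(policy, year) {
  fpd <- policy$flood_protection_days
  nm <- names(fpd)
  if (is.null(nm)) return(unname(fpd[1]))
  if (as.character(year) %in% nm) return(unname(fpd[[as.character(year)]]))
  default <- fpd[nm == ""]
  if (length(default) > 0) unname(default[1]) else Inf
}

policy_active_in_year <- function(policy, year) {
  is.null(policy$years) || year %in% policy$years
}

#' Simulate daily nest fates under competing mortality causes
#'
#' Walks every nest through its 26-day activity window one day at a time.
#' Each day the competing causes are resolved in a fixed order -- flood,
#' trampling, predation, abandonment -- and the first event wins:
#' * on a flood day, unprotected active nests within the flood reach of the
#'   shoreline fail with the flood lethality;
#' * from the cattle release day onward, unprotected nests inside the grazed
#'   zone fail with the daily trampling hazard;
#' * predation occurs with probability `1 - S_it`, where `S_it` is the
#'   inverse-logit of the survival model's linear predictor at the nest's
#'   scaled covariates, scaled nest age `t`, incubation state and year
#'   effect;
#' * abandonment occurs with the daily abandonment hazard.
#' Survivors of all 26 transitions hatch. While a clutch holds dummy eggs
#' the predation and abandonment hazards are rescaled by the dummy-egg
#' multipliers and the nest is immune to its protected cause.
#'
#' The per-nest-day event draws depend only on the scenario seed, never on
#' the policy, so protected and unprotected runs of the same scenario are
#' coupled: enabling a purely protective policy can only save nests.
#'
#' @param nests Nest tibble from [generate_nests()] (or equivalent).
#' @param landscape The landscape the nests live in.
#' @param true_params A [true_parameters()] object.
#' @param config The [scenario_config()] (flood days, cattle schedule,
#'   grazed zone, seed).
#' @param policy Optional [protection_policy()]; `NULL` or a disabled policy
#'   simulates natural fates.
#' @param covariates Optional pre-computed scaled covariates (from the
#'   internal generator design); computed from potential activity windows
#'   when missing.
#' @param u_year Optional named standard-normal year deviates; drawn from
#'   the scenario seed when missing (or taken from
#'   `true_params$year_effects`).
#' @return `nests` with `fate`, `end_day`, `protected_cause`,
#'   `intervention_day` and `artificially_incubated` filled in, and the
#'   realized year effects attached as attribute `"u_year"`.
#' @export
simulate_daily_fates <- function(nests, landscape, true_params, config,
                                 policy = NULL, covariates = NULL,
                                 u_year = NULL) {
  stopifnot(inherits(true_params, "true_parameters"),
            inherits(config, "scenario_config"))
  n <- nrow(nests)
  if (n == 0) return(nests)
  if (is.null(covariates)) covariates <- simulation_covariates(nests, landscape)
  scaled <- covariates
  miss <- !vapply(
    c("Nests", "Q.Nests", "Leks", "Q.Leks", "LayDate", "Path", "Edges",
      "Shore", "dist_shore"),
    function(cl) cl %in% names(scaled), logical(1)
  )
  if (any(miss)) {
    stop("missing covariate(s) for simulation: ",
         paste(c("Nests", "Q.Nests", "Leks", "Q.Leks", "LayDate", "Path",
                 "Edges", "Shore", "dist_shore")[miss], collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(
    scaled[, c("Nests", "LayDate", "Path", "Edges", "Shore")]
  ))
  if (length(bad) > 0) {
    stop("missing covariate value for nest ", scaled$nest_id[bad[1]],
         call. = FALSE)
  }
  beta <- true_params$beta
  if (is.null(u_year)) {
    if (!is.null(true_params$year_effects)) {
      u_year <- stats::setNames(true_params$year_effects,
                                as.character(config$years))
    } else {
      u_year <- with_seed(config$rng_seed + 5L,
                          stats::setNames(stats::rnorm(config$n_years),
                                          as.character(config$years)))
    }
  }
  v_year <- true_params$sigma_year * u_year

  U <- with_seed(config$rng_seed + 3L,
                 array(stats::runif(n * 26 * 4), dim = c(n, 26, 4)))
  relab <- with_seed(config$rng_seed + 4L, stats::runif(2 * n))

  lay <- nests$lay_day
  yr_chr <- as.character(nests$year)
  eta0 <- as.numeric(static_eta(scaled, beta)) + unname(v_year[yr_chr])
  dist_shore <- scaled$dist_shore
  zone <- in_zone(nests$x, nests$y, config$grazed_zone)
  release <- config$cattle_release_day[yr_chr]

  use_policy <- !is.null(policy) && policy$enabled
  prot_cause <- nests$protected_cause %||% rep("none", n)
  prot_cause[is.na(prot_cause)] <- "none"
  interv <- nests$intervention_day %||% rep(NA_integer_, n)
  art_inc <- nests$artificially_incubated %||% rep(FALSE, n)
  art_inc[is.na(art_inc)] <- FALSE
  # Pre-set incubation flags without an intervention day act from day one.
  incub_from <- ifelse(art_inc & is.na(interv), lay + 1L, interv)
  flood_dur <- vapply(nests$year,
                      function(y) flood_duration_for_year(
                        policy %||% config$policy, y),
                      numeric(1))

  alive <- rep(TRUE, n)
  fate <- rep(NA_character_, n)
  end_day <- lay + 26L

  floods <- config$flood_days
  for (d in seq(min(lay) + 1L, max(lay) + 26L)) {
    active <- alive & lay < d & d <= lay + 26L
    if (!any(active)) next
    t_idx <- d - lay  # transition index, valid where active

    if (use_policy && policy$trampling_trigger) {
      for (k in seq_len(config$n_years)) {
        yr <- config$years[k]
        if (!policy_active_in_year(policy, yr)) next
        rel <- unname(config$cattle_release_day[as.character(yr)])
        d_t <- rel - policy$trampling_lead_days
        # clutches present in the grazing area before the cattle arrive are
        # swapped: existing nests on the lead day, later clutches on the
        # day they appear (up to the release day itself)
        if (d >= d_t && d <= rel) {
          des <- alive & nests$year == yr & zone & lay <= d & d <= lay + 26L &
            prot_cause == "none"
          prot_cause[des] <- "trampling"
          interv[des] <- d
          art_inc[des] <- TRUE
          incub_from[des] <- d
        }
      }
    }
    if (use_policy && policy$flood_trigger && nrow(floods) > 0) {
      fl <- floods[floods$day == d, , drop = FALSE]
      for (q in seq_len(nrow(fl))) {
        if (!policy_active_in_year(policy, fl$year[q])) next
        des <- alive & nests$year == fl$year[q] & lay <= d & d <= lay + 26L &
          dist_shore <= fl$reach_m[q] & prot_cause == "none"
        prot_cause[des] <- "flood"
        interv[des] <- d
        art_inc[des] <- flood_dur[des] * 24 > policy$short_protection_hours
        incub_from[des] <- d
      }
    }

    # Dummy eggs in the nest: from intervention day, for flood protections
    # only while the real clutch is in the incubator.
    dummy <- prot_cause != "none" & !is.na(interv) & d >= interv &
      (prot_cause == "trampling" | d < interv + flood_dur)

    # 1. Flood.
    if (nrow(floods) > 0) {
      fl <- floods[floods$day == d, , drop = FALSE]
      for (q in seq_len(nrow(fl))) {
        cand <- active & nests$year == fl$year[q] &
          dist_shore <= fl$reach_m[q] &
          !(prot_cause == "flood" & !is.na(interv) & d >= interv &
              d < interv + flood_dur)
        hit <- cand & U[cbind(seq_len(n), pmin(pmax(t_idx, 1L), 26L), 1L)] <
          true_params$flood_lethality
        fate[hit] <- "flooded"; end_day[hit] <- d; alive[hit] <- FALSE
      }
      active <- active & alive
    }
    # 2. Trampling.
    if (true_params$trampling_hazard > 0) {
      cand <- active & zone & d >= release &
        !(prot_cause == "trampling" & !is.na(interv) & d >= interv)
      hit <- cand & U[cbind(seq_len(n), pmin(pmax(t_idx, 1L), 26L), 2L)] <
        true_params$trampling_hazard
      fate[hit] <- "trampled"; end_day[hit] <- d; alive[hit] <- FALSE
      active <- active & alive
    }
    # 3. Predation from the survival model.
    incub_on <- art_inc & !is.na(incub_from) & d >= incub_from
    eta <- eta0 + beta["NestAge"] * age_scale(t_idx) +
      beta["Incubation"] * as.numeric(incub_on)
    if (any(!is.finite(eta[active]))) {
      stop("non-finite linear predictor for nest ",
           nests$nest_id[active & !is.finite(eta)][1], call. = FALSE)
    }
    h_pred <- (1 - inv_logit(eta)) *
      ifelse(dummy, true_params$dummy_predation_mult, 1)
    hit <- active & U[cbind(seq_len(n), pmin(pmax(t_idx, 1L), 26L), 3L)] < h_pred
    fate[hit] <- "predated"; end_day[hit] <- d; alive[hit] <- FALSE
    active <- active & alive
    # 4. Abandonment.
    if (true_params$abandonment_hazard > 0) {
      h_ab <- true_params$abandonment_hazard *
        ifelse(dummy, true_params$dummy_abandonment_mult, 1)
      hit <- active & U[cbind(seq_len(n), pmin(pmax(t_idx, 1L), 26L), 4L)] < h_ab
      fate[hit] <- "abandoned"; end_day[hit] <- d; alive[hit] <- FALSE
    }
  }
  fate[alive] <- "hatched"
  end_day[alive] <- lay[alive] + 26L

  # Interventions that never happened (nest failed before its designated
  # day) are cleared.
  void <- prot_cause != "none" & !is.na(interv) & end_day < interv
  prot_cause[void] <- "none"; interv[void] <- NA_integer_; art_inc[void] <- FALSE

  # Observation layer: some failures lack an attributable cause, some lack
  # any evidence; some hatches are never confirmed ("escaped").
  failed <- fate %in% c("predated", "flooded", "trampled", "abandoned")
  r1 <- relab[seq_len(n)]; r2 <- relab[n + seq_len(n)]
  to_ud <- failed & r1 < config$prob_unknown_dead
  to_un <- failed & !to_ud &
    r1 < config$prob_unknown_dead + config$prob_unknown
  fate[to_ud] <- "unknown_dead"
  fate[to_un] <- "unknown"
  to_esc <- fate == "hatched" & r2 < config$prob_escaped
  fate[to_esc] <- "escaped"

  out <- nests
  out$fate <- fate
  out$end_day <- as.integer(end_day)
  out$protected_cause <- prot_cause
  out$intervention_day <- as.integer(interv)
  out$artificially_incubated <- art_inc
  attr(out, "u_year") <- u_year
  out
}

#' Apply (or re-apply) the clutch-protection policy
#'
#' Re-runs the daily fate walk with the given policy using the same
#' scenario-seeded event draws, so a disabled policy returns the input fates
#' unchanged and an enabled, purely protective policy (dummy-egg multipliers
#' at or below 1) can only increase the number of hatched nests.
#'
#' @inheritParams simulate_daily_fates
#' @param policy A [protection_policy()].
#' @return Nest tibble with protection fields and (possibly changed) fates.
#' @export
apply_protection_policy <- function(nests, policy, landscape, true_params,
                                    config, covariates = NULL, u_year = NULL) {
  stopifnot(inherits(policy, "protection_policy"))
  base <- nests
  base$fate <- NA_character_
  base$end_day <- NA_integer_
  base$protected_cause <- "none"
  base$intervention_day <- NA_integer_
  base$artificially_incubated <- FALSE
  out <- simulate_daily_fates(base, landscape, true_params, config,
                              policy = policy, covariates = covariates,
                              u_year = u_year %||% attr(nests, "u_year"))
  out
}

#' Simulate a complete nest study
#'
#' Runs the full generator: landscape, nests, generator covariates, the
#' daily fate walk under the configured protection policy.
#'
#' @param config A [scenario_config()].
#' @return A list of class `"ruff_study"` with `nests` (fates and
#'   protection filled), `landscape`, `covariates` (the scaled generator
#'   design, including raw distances and the year-wise scaling attributes),
#'   `truth` (true parameters plus the realized year deviates `u_year`) and
#'   `config`.
#' @export
#' @examples
#' study <- simulate_nest_study(scenario_config(n_years = 2,
#'                                              nests_per_year = 15,
#'                                              rng_seed = 11))
#' dplyr::count(study$nests, fate)
simulate_nest_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  landscape <- generate_landscape(config)
  nests <- generate_nests(config, landscape)
  if ((config$incubated_fraction %||% 0) > 0) {
    flag <- with_seed(config$rng_seed + 6L,
                      stats::runif(nrow(nests)) < config$incubated_fraction)
    nests$artificially_incubated <- flag
  }
  covariates <- simulation_covariates(nests, landscape)
  nests <- simulate_daily_fates(nests, landscape, config$true_params, config,
                                policy = config$policy,
                                covariates = covariates)
  structure(
    list(
      nests = nests, landscape = landscape, covariates = covariates,
      truth = list(true_params = config$true_params,
                   u_year = attr(nests, "u_year"),
                   v_year = config$true_params$sigma_year *
                     attr(nests, "u_year")),
      config = config
    ),
    class = "ruff_study"
  )
}

#' @export
print.ruff_study <- function(x, ...) {
  cat("<ruff_study>\n")
  tab <- table(x$nests$fate)
  cat(sprintf("  %d nests over %d years; fates: %s\n", nrow(x$nests),
              x$config$n_years,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  %d protected nest(s) (%d artificially incubated > 24 h)\n",
              sum(x$nests$protected_cause != "none"),
              sum(x$nests$artificially_incubated)))
  invisible(x)
}

#' Read and write nest tables as CSV
#'
#' @param nests Nest tibble.
#' @param path File path.
#' @return `write_nest_csv()` returns `path` invisibly; `read_nest_csv()`
#'   returns a tibble with the column types used throughout the package.
#' @export
write_nest_csv <- function(nests, path) {
  readr::write_csv(nests, path)
  invisible(path)
}

#' @rdname write_nest_csv
#' @export
read_nest_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      nest_id = readr::col_character(),
      year = readr::col_integer(),
      lay_day = readr::col_integer(),
      end_day = readr::col_integer(),
      fate = readr::col_character(),
      clutch_size = readr::col_integer(),
      protected_cause = readr::col_character(),
      intervention_day = readr::col_integer(),
      artificially_incubated = readr::col_logical(),
      .default = readr::col_double()
    )
  )
}
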