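#' Simulator ground truth for the daily survival process
#'
#' Bundles the coefficients of the daily survival logit model together with
#' the cause-specific hazard layers that the model does not describe:
#' flood lethality on storm-surge days, a daily trampling hazard inside the
#' grazed zone after cattle release, a daily abandonment hazard, and the
#' hazard multipliers that apply once a clutch has been swapped for dummy
#' eggs. All coefficients act on within-year standardised covariates, on the
#' log-odds scale.
#'
#' Defaults are calibration choices, not field estimates: the coefficient
#' values give a survival surface with its maximum at intermediate
#' nest-to-nest distances and declining survival with nest age, and the
#' cause hazards are set so that a simulated season produces fate shares of
#' the order observed on grazed Baltic coastal meadows (roughly 40%-50% of
#' nests hatching, predation the dominant failure cause).
#'
#' @param beta Named numeric vector of logit-scale coefficients; names must
#'   be `r paste0('"', paste(COEF_NAMES, collapse = '", "'), '"')`.
#'   Partial vectors are merged over the defaults.
#' @param sigma_year Standard deviation of the year random effect (>= 0; a
#'   value of 0 switches annual variation off).
#' @param year_effects Optional vector of standard-normal year deviates
#'   `u_year` (one per simulated year). When `NULL` they are drawn when the
#'   study is simulated; the realized values are recorded in the output.
#' @param flood_lethality Probability that an unprotected active nest within
#'   reach of the shoreline fails on a flood day.
#' @param trampling_hazard Daily failure probability from trampling for an
#'   unprotected nest inside the grazed zone after cattle release.
#' @param abandonment_hazard Daily probability of abandonment.
#' @param dummy_predation_mult,dummy_abandonment_mult Multipliers applied to
#'   the predation and abandonment hazards of a nest while it holds dummy
#'   eggs. Values below 1 protect, values above 1 harm.
#'
#' @return A list of class `"true_parameters"`.
#' @export
#' @examples
#' true_parameters(beta = c(NestAge = -0.5), sigma_year = 0.3)
true_parameters <- function(beta = NULL,
                            sigma_year = 0.5,
                            year_effects = NULL,
                            flood_lethality = 0.9,
                            trampling_hazard = 0.04,
                            abandonment_hazard = 0.005,
                            dummy_predation_mult = 0.5,
                            dummy_abandonment_mult = 1.5) {
  base <- c(
    Intercept = 4.6, Nests = 1.0, Q.Nests = -0.4, Leks = 0, Q.Leks = 0,
    LayDate = 0, NestAge = -0.8, Incubation = 0, Path = 0, Edges = 0, Shore = 0
  )
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% COEF_NAMES)) {
      stop("`beta` must be named with coefficient names: ",
           paste(COEF_NAMES, collapse = ", "), call. = FALSE)
    }
    base[names(beta)] <- beta
  }
  stopifnot(sigma_year >= 0, flood_lethality >= 0, flood_lethality <= 1,
            trampling_hazard >= 0, trampling_hazard <= 1,
            abandonment_hazard >= 0, abandonment_hazard <= 1,
            dummy_predation_mult >= 0, dummy_abandonment_mult >= 0)
  structure(
    list(
      beta = base, sigma_year = sigma_year, year_effects = year_effects,
      flood_lethality = flood_lethality, trampling_hazard = trampling_hazard,
      abandonment_hazard = abandonment_hazard,
      dummy_predation_mult = dummy_predation_mult,
      dummy_abandonment_mult = dummy_abandonment_mult
    ),
    class = "true_parameters"
  )
}

#' Clutch-protection policy
#'
#' Describes the dummy-egg intervention: on a (perfectly forecast) flood day
#' every active nest within the flood reach has its clutch swapped for
#' plastic dummies, and a fixed number of days before cattle release every
#' active nest inside the grazed zone is protected the same way. Protections
#' that keep the real clutch in an incubator for no longer than
#' `short_protection_hours` are not counted as artificially incubated.
#'
#' @param enabled Master switch; when `FALSE` the simulated fates are
#'   identical to the unprotected run.
#' @param flood_trigger,trampling_trigger Switch the two triggers separately.
#' @param trampling_lead_days Days before the cattle release day at which
#'   clutches in the grazed zone are swapped (>= 0).
#' @param short_protection_hours Threshold below which a protection does not
#'   count as artificial incubation (default 24 h).
#' @param flood_protection_days Duration, in days, that a flood-protected
#'   clutch stays in the incubator. Either a single value or a named vector
#'   by year; `Inf` means until hatching. A 1-day value reproduces seasons in
#'   which clutches were returned the day after the surge and are therefore
#'   not flagged as artificially incubated.
#' @param years Years in which the intervention was carried out (`NULL` =
#'   every year). Floods in other years hit unprotected nests.
#'
#' @return A list of class `"protection_policy"`.
#' @export
protection_policy <- function(enabled = TRUE,
                              flood_trigger = TRUE,
                              trampling_trigger = TRUE,
                              trampling_lead_days = 3,
                              short_protection_hours = 24,
                              flood_protection_days = Inf,
                              years = NULL) {
  stopifnot(trampling_lead_days >= 0, short_protection_hours > 0,
            all(flood_protection_days > 0))
  structure(
    list(
      enabled = isTRUE(enabled), flood_trigger = isTRUE(flood_trigger),
      trampling_trigger = isTRUE(trampling_trigger),
      trampling_lead_days = trampling_lead_days,
      short_protection_hours = short_protection_hours,
      flood_protection_days = flood_protection_days,
      years = if (is.null(years)) NULL else as.integer(years)
    ),
    class = "protection_policy"
  )
}

#' Scenario configuration for the synthetic nest study
#'
#' Holds everything the generator needs: study dimensions, landscape
#' geometry, the true survival process, flood days, the cattle schedule, the
#' grazed zone, the protection policy and the seed. Defaults emulate a
#' six-season study of ~275 ruff nests on a coastal meadow: a roughly 3 km
#' strip with the shoreline and the meadow edge on opposite sides, paths
#' crossing it, a dozen leks, three storm-surge floods across the six years
#' and cattle released in early June; the protection policy runs in four of
#' the six seasons.
#'
#' Day-of-season 0 is the first possible lay day (about mid-May); lay days
#' span `[0, season_length - 27]` so every nest can complete its 26-day
#' activity window inside the season.
#'
#' @param n_years Number of breeding seasons.
#' @param years Integer year labels (length `n_years`).
#' @param nests_per_year Nests per season; scalar or length `n_years`.
#' @param season_length Days in the season frame (>= 27).
#' @param meadow_width,meadow_height Meadow extent in metres. The meadow edge
#'   runs along `y = 0`, the shoreline along `y = meadow_height`.
#' @param nesting_band `c(ymin, ymax)` band (m) in which nests and leks lie.
#' @param n_paths Number of paths crossing the meadow.
#' @param n_leks Number of lek points.
#' @param lek_x_range Horizontal range (m) in which leks are placed; leks
#'   cluster in part of the meadow so that lek distances vary widely.
#' @param nn_target_m Target scale (m) for the nearest-nest distance of the
#'   generated point pattern; the hard-core inhibition radius is derived
#'   from it unless `min_nest_spacing` overrides it.
#' @param min_nest_spacing Hard-core inhibition radius (m) between same-year
#'   nests (`NULL`: 0.75 x `nn_target_m`).
#' @param cluster_weight Fraction of nests placed near a lek rather than
#'   uniformly over the band (nests aggregate around display sites).
#' @param cluster_sd Gaussian scatter (m) of lek-clustered nests around
#'   their cluster centre.
#' @param cluster_offset_sd Displacement (m) of each cluster centre from
#'   its lek (females nest near, not on, display sites).
#' @param clutch_p4 Probability of a 4-egg clutch (otherwise 3).
#' @param true_params A [true_parameters()] object.
#' @param flood_days Tibble/data frame with columns `year`, `day`,
#'   `reach_m`: storm-surge days and how far (m) from the shoreline the
#'   water reaches.
#' @param cattle_release_day Day-of-season of cattle release; scalar or
#'   named vector by year.
#' @param grazed_zone Named vector `c(xmin, xmax, ymin, ymax)` (m) of the
#'   spring-grazing area.
#' @param policy A [protection_policy()] object.
#' @param incubated_fraction Fraction of nests flagged as artificially
#'   incubated from laying onward, independent of the protection policy
#'   (used for experiments that need the incubation covariate identified
#'   without the policy's triggers; 0 in the default study).
#' @param prob_unknown_dead Probability that a failed nest is found with
#'   evidence of failure but no attributable cause.
#' @param prob_unknown Probability that a failed nest's fate is recorded as
#'   fully unknown.
#' @param prob_escaped Probability that a hatched nest is recorded as
#'   "escaped" (likely hatched, hatch day unobserved).
#' @param rng_seed Integer seed fixing all randomness of the scenario.
#'
#' @return A list of class `"scenario_config"`.
#' @export
#' @examples
#' cfg <- scenario_config(n_years = 2, nests_per_year = 20, rng_seed = 7)
#' cfg$years
scenario_config <- function(n_years = 6,
                            years = seq(2018, length.out = n_years),
                            nests_per_year = c(40, 52, 44, 50, 43, 46),
                            season_length = 57,
                            meadow_width = 3000,
                            meadow_height = 1300,
                            nesting_band = c(400, 1000),
                            n_paths = 9,
                            n_leks = 12,
                            lek_x_range = c(150, 2100),
                            nn_target_m = 121.2,
                            min_nest_spacing = NULL,
                            cluster_weight = 0.9,
                            cluster_sd = 70,
                            cluster_offset_sd = 250,
                            clutch_p4 = 0.8,
                            true_params = true_parameters(),
                            flood_days = NULL,
                            cattle_release_day = 22,
                            grazed_zone = c(xmin = 0, xmax = 800,
                                            ymin = 0, ymax = meadow_height),
                            policy = protection_policy(
                              years = c(2018L, 2019L, 2021L, 2022L),
                              flood_protection_days = c("2021" = 1)
                            ),
                            incubated_fraction = 0,
                            prob_unknown_dead = 0.06,
                            prob_unknown = 0.02,
                            prob_escaped = 0.01,
                            rng_seed = 1L) {
  stopifnot(n_years >= 1, season_length >= 27, meadow_width > 0,
            meadow_height > 0, n_leks >= 0, n_paths >= 1,
            nn_target_m > 0, clutch_p4 >= 0, clutch_p4 <= 1,
            cluster_weight >= 0, cluster_weight <= 1, cluster_sd > 0,
            cluster_offset_sd >= 0)
  if (is.null(min_nest_spacing)) min_nest_spacing <- 0.33 * nn_target_m
  stopifnot(min_nest_spacing >= 0)
  years <- as.integer(years)
  stopifnot(length(years) == n_years)
  if (length(nests_per_year) == 1L) {
    nests_per_year <- rep(nests_per_year, n_years)
  }
  nests_per_year <- as.integer(nests_per_year[seq_len(n_years)])
  stopifnot(all(nests_per_year >= 0))
  if (is.null(flood_days)) {
    # Three surge events across the default six seasons; the 2020 surge
    # falls in a season without intervention. Only rows whose year is
    # simulated apply.
    flood_days <- tibble::tibble(
      year = c(2019L, 2020L, 2021L), day = c(16L, 14L, 12L),
      reach_m = c(620, 850, 620)
    )
  }
  flood_days <- tibble::as_tibble(flood_days)
  stopifnot(all(c("year", "day", "reach_m") %in% names(flood_days)),
            all(flood_days$reach_m >= 0))
  if (length(cattle_release_day) == 1L && is.null(names(cattle_release_day))) {
    cattle_release_day <- stats::setNames(rep(cattle_release_day, n_years),
                                          as.character(years))
  }
  stopifnot(inherits(true_params, "true_parameters"),
            inherits(policy, "protection_policy"))
  structure(
    list(
      n_years = as.integer(n_years), years = years,
      nests_per_year = nests_per_year,
      season_length = as.integer(season_length),
      meadow_width = meadow_width, meadow_height = meadow_height,
      nesting_band = nesting_band, n_paths = as.integer(n_paths),
      n_leks = as.integer(n_leks), lek_x_range = lek_x_range,
      nn_target_m = nn_target_m, min_nest_spacing = min_nest_spacing,
      cluster_weight = cluster_weight, cluster_sd = cluster_sd,
      cluster_offset_sd = cluster_offset_sd,
      clutch_p4 = clutch_p4,
      true_params = true_params, flood_days = flood_days,
      cattle_release_day = cattle_release_day, grazed_zone = grazed_zone,
      policy = policy, incubated_fraction = incubated_fraction,
      prob_unknown_dead = prob_unknown_dead, prob_unknown = prob_unknown,
      prob_escaped = prob_escaped,
      rng_seed = as.integer(rng_seed)
    ),
    class = "scenario_config"
  )
}

#' Configuration preset for parameter-recovery experiments
#'
#' Returns a [scenario_config()] in which every mortality cause other than
#' the logit survival model is switched off (no floods, no trampling, no
#' abandonment, no fate-recording noise, protection disabled). All failures
#' then flow through the daily survival model, so the generating coefficients
#' are exactly the quantities a fitted model should recover.
#'
#' @param rng_seed Integer seed.
#' @param ... Passed on to [scenario_config()].
#' @return A `"scenario_config"`.
#' @export
recovery_config <- function(rng_seed = 1L, ...) {
  args <- list(...)
  tp <- args$true_params %||% true_parameters()
  tp$flood_lethality <- 0
  tp$trampling_hazard <- 0
  tp$abandonment_hazard <- 0
  args$true_params <- tp
  args$flood_days <- tibble::tibble(year = integer(), day = integer(),
                                    reach_m = numeric())
  args$policy <- protection_policy(enabled = FALSE)
  args$prob_unknown_dead <- 0
  args$prob_unknown <- 0
  args$prob_escaped <- 0
  args$incubated_fraction <- args$incubated_fraction %||% 0.15
  args$rng_seed <- rng_seed
  do.call(scenario_config, args)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d years (%s), %d nests, season of %d days\n",
              x$n_years, paste(range(x$years), collapse = "-"),
              sum(x$nests_per_year), x$season_length))
  cat(sprintf("  meadow %g x %g m, %d paths, %d leks\n",
              x$meadow_width, x$meadow_height, x$n_paths, x$n_leks))
  cat(sprintf("  %d flood day(s); cattle release day %s; protection %s\n",
              nrow(x$flood_days),
              paste(unique(x$cattle_release_day), collapse = "/"),
              if (x$policy$enabled) "enabled" else "disabled"))
  cat(sprintf("  seed %d\n", x$rng_seed))
  invisible(x)
}

#' Read and write scenario configurations as YAML
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_yaml()` returns `path` invisibly;
#'   `read_scenario_yaml()` returns a `"scenario_config"`.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$true_params <- unclass(x$true_params)
  x$true_params$beta <- as.list(x$true_params$beta)
  x$policy <- unclass(x$policy)
  # yaml drops names on short named vectors; store durations as a map
  x$policy$flood_protection_days <- as.list(x$policy$flood_protection_days)
  x$flood_days <- as.list(as.data.frame(x$flood_days))
  x$cattle_release_day <- as.list(x$cattle_release_day)
  x$grazed_zone <- as.list(x$grazed_zone)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  tp <- x$true_params
  beta <- unlist(tp$beta)
  cfg <- scenario_config(
    n_years = x$n_years, years = x$years, nests_per_year = x$nests_per_year,
    season_length = x$season_length, meadow_width = x$meadow_width,
    meadow_height = x$meadow_height, nesting_band = unlist(x$nesting_band),
    n_paths = x$n_paths, n_leks = x$n_leks,
    lek_x_range = unlist(x$lek_x_range),
    nn_target_m = x$nn_target_m, min_nest_spacing = x$min_nest_spacing,
    cluster_weight = x$cluster_weight, cluster_sd = x$cluster_sd,
    cluster_offset_sd = x$cluster_offset_sd, clutch_p4 = x$clutch_p4,
    true_params = true_parameters(
      beta = beta, sigma_year = tp$sigma_year,
      year_effects = tp$year_effects,
      flood_lethality = tp$flood_lethality,
      trampling_hazard = tp$trampling_hazard,
      abandonment_hazard = tp$abandonment_hazard,
      dummy_predation_mult = tp$dummy_predation_mult,
      dummy_abandonment_mult = tp$dummy_abandonment_mult
    ),
    flood_days = tibble::as_tibble(lapply(x$flood_days, unlist)),
    cattle_release_day = unlist(x$cattle_release_day),
    grazed_zone = unlist(x$grazed_zone),
    policy = protection_policy(
      enabled = x$policy$enabled, flood_trigger = x$policy$flood_trigger,
      trampling_trigger = x$policy$trampling_trigger,
      trampling_lead_days = x$policy$trampling_lead_days,
      short_protection_hours = x$policy$short_protection_hours,
      flood_protection_days = unlist(x$policy$flood_protection_days),
      years = unlist(x$policy$years)
    ),
    incubated_fraction = x$incubated_fraction %||% 0,
    prob_unknown_dead = x$prob_unknown_dead, prob_unknown = x$prob_unknown,
    prob_escaped = x$prob_escaped, rng_seed = x$rng_seed
  )
  cfg
}
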