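# helpers used only here -----------------------------------------------------

# scaled-covariate table for hand-built cohorts (bypasses the landscape)
flat_covariates <- function(nests, z_nests = 0, dist_shore = 1000) {
  tibble::tibble(
    nest_id = nests$nest_id, year = nests$year,
    Nests = z_nests, Q.Nests = z_nests^2, Leks = 0, Q.Leks = 0,
    LayDate = 0, Path = 0, Edges = 0, Shore = 0,
    dist_shore = dist_shore
  )
}

# single-year config with every side-channel off (no policy, no fate
# relabelling, no floods unless supplied)
bare_config <- function(...) {
  dots <- list(...)
  base <- list(
    n_years = 1, years = 2018L, nests_per_year = 1,
    policy = protection_policy(enabled = FALSE),
    prob_unknown_dead = 0, prob_unknown = 0, prob_escaped = 0,
    flood_days = tibble::tibble(year = integer(), day = integer(),
                                reach_m = numeric())
  )
  base[names(dots)] <- dots
  do.call(scenario_config, base)
}

manual_nests <- function(n, lay_day = 0L, year = 2018L) {
  tibble::tibble(
    nest_id = sprintf("m%04d", seq_len(n)), year = year,
    x = runif(n, 0, 3000), y = runif(n, 400, 1000),
    lay_day = lay_day, end_day = NA_integer_, fate = NA_character_,
    clutch_size = 4L, protected_cause = "none",
    intervention_day = NA_integer_, artificially_incubated = FALSE
  )
}

# ----------------------------------------------------------------------------

test_that("nest generation respects counts, lay window and seeds", {
  cfg <- scenario_config(n_years = 2, years = 2018:2019,
                         nests_per_year = c(15, 20), rng_seed = 2)
  land <- generate_landscape(cfg)
  nests <- generate_nests(cfg, land)
  expect_equal(nrow(nests), 35)
  expect_equal(as.integer(table(nests$year)), c(15L, 20L))
  expect_true(all(nests$lay_day >= 0 &
                    nests$lay_day <= cfg$season_length - 27))
  expect_true(all(nests$clutch_size %in% c(3L, 4L)))
  expect_true(all(is.na(nests$fate)))
  # hard-core spacing holds within each year
  for (yr in unique(nests$year)) {
    xy <- nests[nests$year == yr, c("x", "y")]
    expect_gt(min(dist(xy)), cfg$min_nest_spacing)
  }
  # same seed reproduces; different seed moves coordinates, same count
  expect_identical(nests, generate_nests(cfg, land))
  cfg2 <- scenario_config(n_years = 2, years = 2018:2019,
                          nests_per_year = c(15, 20), rng_seed = 3)
  nests2 <- generate_nests(cfg2, generate_landscape(cfg2))
  expect_equal(nrow(nests2), 35)
  expect_false(identical(nests$x, nests2$x))
  # zero nests is an empty table, not an error
  cfg0 <- scenario_config(n_years = 1, years = 2018L, nests_per_year = 0,
                          rng_seed = 1)
  expect_equal(nrow(generate_nests(cfg0, generate_landscape(cfg0))), 0)
})

test_that("generated point pattern hits the nearest-nest distance scale", {
  # ~1000 nests as replicate seasons of the configured process; the mean
  # daily nearest-neighbour distance over potential activity windows must
  # sit within +-30% of the configured target scale
  cfg <- scenario_config(
    n_years = 22, years = 2001:2022, nests_per_year = 46,
    flood_days = tibble::tibble(year = integer(), day = integer(),
                                reach_m = numeric()),
    rng_seed = 9
  )
  nests <- generate_nests(cfg, generate_landscape(cfg))
  expect_gte(nrow(nests), 1000)
  nests$end_day <- nests$lay_day + 26L
  nn <- mean(mean_daily_nearest_nest_distance(nests), na.rm = TRUE)
  expect_gt(nn, 0.7 * cfg$nn_target_m)
  expect_lt(nn, 1.3 * cfg$nn_target_m)
})

test_that("all hazards zero means every nest hatches at day 26", {
  set.seed(1)
  nests <- manual_nests(40, lay_day = sample(0:20, 40, replace = TRUE))
  cfg <- bare_config(rng_seed = 5)
  tp <- true_parameters(beta = c(Intercept = 40), sigma_year = 0,
                        flood_lethality = 0, trampling_hazard = 0,
                        abandonment_hazard = 0)
  out <- simulate_daily_fates(nests, NULL, tp, cfg,
                              covariates = flat_covariates(nests),
                              u_year = c("2018" = 0))
  expect_true(all(out$fate == "hatched"))
  expect_true(all(out$end_day == out$lay_day + 26L))
})

test_that("predation-only cohort with constant S matches the closed form", {
  set.seed(2)
  n <- 2000
  nests <- manual_nests(n)
  cfg <- bare_config(rng_seed = 8)
  tp <- true_parameters(beta = c(Intercept = qlogis(0.9), Nests = 0,
                                 Q.Nests = 0, NestAge = 0),
                        sigma_year = 0, flood_lethality = 0,
                        trampling_hazard = 0, abandonment_hazard = 0)
  out <- simulate_daily_fates(nests, NULL, tp, cfg,
                              covariates = flat_covariates(nests),
                              u_year = c("2018" = 0))
  p_true <- 0.9^26
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(out$fate == "hatched") - p_true), 3 * se)
})

test_that("daily failure rates converge to 1 - inv_logit(eta)", {
  # three covariate points, predation-only, age effect off so the daily
  # hazard is constant within a cohort
  set.seed(3)
  cfg <- bare_config(rng_seed = 13)
  for (z in c(-1, 0, 1)) {
    n <- 5000
    nests <- manual_nests(n)
    tp <- true_parameters(beta = c(Intercept = 2, Nests = 1, Q.Nests = -0.4,
                                   NestAge = 0),
                          sigma_year = 0, flood_lethality = 0,
                          trampling_hazard = 0, abandonment_hazard = 0)
    out <- simulate_daily_fates(nests, NULL, tp, cfg,
                                covariates = flat_covariates(nests, z_nests = z),
                                u_year = c("2018" = 0))
    h_true <- 1 - plogis(2 + z - 0.4 * z^2)
    exposure <- sum(out$end_day - out$lay_day)
    rate <- sum(out$fate != "hatched") / exposure
    se <- sqrt(h_true * (1 - h_true) / exposure)
    expect_lt(abs(rate - h_true), 3 * se)
  }
})

test_that("a full-lethality flood kills every unprotected nest in reach", {
  nests <- manual_nests(30, lay_day = rep(c(0L, 20L), 15))
  cov <- flat_covariates(nests, dist_shore = rep(c(50, 500), each = 15))
  cfg <- bare_config(
    rng_seed = 4,
    flood_days = tibble::tibble(year = 2018L, day = 10L, reach_m = 100)
  )
  tp <- true_parameters(beta = c(Intercept = 40), sigma_year = 0,
                        flood_lethality = 1, trampling_hazard = 0,
                        abandonment_hazard = 0)
  out <- simulate_daily_fates(nests, NULL, tp, cfg, covariates = cov,
                              u_year = c("2018" = 0))
  active_in_reach <- cov$dist_shore <= 100 & nests$lay_day < 10 &
    10 <= nests$lay_day + 26
  expect_true(all(out$fate[active_in_reach] == "flooded"))
  expect_true(all(out$end_day[active_in_reach] == 10))
  expect_true(all(out$fate[!active_in_reach] == "hatched"))
})

test_that("every simulated nest gets exactly one fate inside the window", {
  st <- simulate_nest_study(scenario_config(rng_seed = 17))
  expect_true(all(st$nests$fate %in% c("hatched", "predated", "flooded",
                                       "trampled", "abandoned",
                                       "unknown_dead", "unknown", "escaped")))
  expose <- st$nests$end_day - st$nests$lay_day
  expect_true(all(expose >= 1 & expose <= 26))
})

test_that("the full study is byte-level reproducible under a fixed seed", {
  cfg <- scenario_config(rng_seed = 23)
  s1 <- simulate_nest_study(cfg)
  s2 <- simulate_nest_study(cfg)
  expect_identical(s1$nests, s2$nests)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_nest_csv(s1$nests, f1); write_nest_csv(s2$nests, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("a disabled policy returns the natural fates unchanged", {
  cfg <- scenario_config(rng_seed = 19)
  land <- generate_landscape(cfg)
  nests <- generate_nests(cfg, land)
  cov <- ruffsurv:::simulation_covariates(nests, land)
  natural <- simulate_daily_fates(nests, land, cfg$true_params, cfg,
                                  policy = NULL, covariates = cov)
  off <- apply_protection_policy(natural, protection_policy(enabled = FALSE),
                                 land, cfg$true_params, cfg, covariates = cov)
  expect_identical(as.data.frame(natural), as.data.frame(off))
})

test_that("flood-protected nests never drown after their intervention", {
  st <- simulate_nest_study(scenario_config(rng_seed = 29))
  prot <- st$nests[st$nests$protected_cause == "flood", ]
  expect_gt(nrow(prot), 0)
  drowned_after <- prot$fate == "flooded" & prot$end_day >= prot$intervention_day
  expect_true(!any(drowned_after))
})

test_that("1-day flood protections are not counted as artificially incubated", {
  cfg <- scenario_config(
    rng_seed = 37,
    policy = protection_policy(flood_protection_days = 1)
  )
  st <- simulate_nest_study(cfg)
  prot <- st$nests[st$nests$protected_cause == "flood", ]
  expect_gt(nrow(prot), 0)
  expect_true(all(!prot$artificially_incubated))
  # trampling protections run to hatching and do count
  tr <- st$nests[st$nests$protected_cause == "trampling", ]
  expect_true(all(tr$artificially_incubated))
})

test_that("a purely protective policy never loses hatched nests", {
  for (seed in c(41, 43, 47)) {
    tp <- true_parameters(dummy_predation_mult = 0.5,
                          dummy_abandonment_mult = 1)
    cfg_off <- scenario_config(rng_seed = seed, true_params = tp,
                               policy = protection_policy(enabled = FALSE))
    cfg_on <- scenario_config(rng_seed = seed, true_params = tp)
    n_off <- sum(simulate_nest_study(cfg_off)$nests$fate == "hatched")
    n_on <- sum(simulate_nest_study(cfg_on)$nests$fate == "hatched")
    expect_gte(n_on, n_off)
  }
})

test_that("missing covariates are reported with the nest id", {
  nests <- manual_nests(3)
  cov <- flat_covariates(nests)
  cov$Nests[2] <- NA
  cfg <- bare_config(rng_seed = 1)
  expect_error(
    simulate_daily_fates(nests, NULL, true_parameters(), cfg,
                         covariates = cov, u_year = c("2018" = 0)),
    "m0002"
  )
})

test_that("scenario YAML round trip preserves the configuration", {
  cfg <- scenario_config(rng_seed = 53)
  f <- tempfile(fileext = ".yaml")
  write_scenario_yaml(cfg, f)
  cfg2 <- read_scenario_yaml(f)
  expect_equal(cfg2$years, cfg$years)
  expect_equal(cfg2$nests_per_year, cfg$nests_per_year)
  expect_equal(cfg2$true_params$beta, cfg$true_params$beta)
  expect_equal(cfg2$policy$flood_protection_days,
               cfg$policy$flood_protection_days)
  expect_equal(cfg2$flood_days$reach_m, cfg$flood_days$reach_m)
  # identical simulation from the round-tripped config
  expect_identical(simulate_nest_study(cfg)$nests,
                   simulate_nest_study(cfg2)$nests)
  unlink(f)
})
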