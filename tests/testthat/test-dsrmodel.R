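test_that("daily survival probability matches the logistic closed form", {
  b <- c(Intercept = 3, NestAge = -1)
  expect_equal(daily_survival_probability(c(), 0, c(Intercept = 0)), 0.5)
  expect_equal(daily_survival_probability(c(), 0, b), plogis(3),
               tolerance = 1e-6)
  expect_equal(daily_survival_probability(c(), 1, b), plogis(2),
               tolerance = 1e-6)
  # spot values quoted to 5 decimals
  expect_equal(round(daily_survival_probability(c(), 0, b), 5), 0.95257)
  expect_equal(round(daily_survival_probability(c(), 1, b), 5), 0.88080)
  # covariates and year effect enter additively
  expect_equal(
    daily_survival_probability(c(Nests = 2), 0,
                               c(Intercept = 1, Nests = 0.5), year_effect = 1),
    plogis(3)
  )
  expect_error(daily_survival_probability(c(), Inf, b), "non-finite")
})

test_that("survival decreases with age when the age coefficient is negative", {
  b <- c(Intercept = 2, NestAge = -0.8)
  s <- daily_survival_probability(c(), age_scaled(1:26), b)
  expect_true(all(diff(s) < 0))
})

test_that("log-likelihood matches direct arithmetic", {
  nests <- toy_nests(1)
  nests$lay_day <- 0L; nests$end_day <- 4L; nests$fate <- "predated"
  design <- tidyr::expand_grid(nests[, c("nest_id", "year")], t = 1:26)
  design$Intercept <- 1
  h <- encode_histories(cap_activity(nests), "overall")
  beta <- c(Intercept = qlogis(0.9))
  # alive 3 days then fails: 3 ln 0.9 + ln 0.1
  expect_equal(scenario_log_likelihood(h, design, beta),
               3 * log(0.9) + log(0.1))
  expect_equal(round(scenario_log_likelihood(h, design, beta), 5), -2.61867)
  # censored after day 3: survival terms only
  h_cens <- encode_histories(cap_activity(nests), "no_predation")
  expect_equal(round(scenario_log_likelihood(h_cens, design, beta), 5),
               -0.31608)
  # S = 1 on all-alive histories gives 0
  nests$fate <- "hatched"; nests$end_day <- 26L
  h_alive <- encode_histories(cap_activity(nests), "overall")
  expect_equal(
    scenario_log_likelihood(h_alive, design, c(Intercept = 100)), 0
  )
})

test_that("log-likelihood equals the brute-force per-day product", {
  for (seed in 1:25) {
    rs <- random_history_set(seed)
    expect_lt(
      abs(scenario_log_likelihood(rs$histories, rs$design, rs$beta) -
            bf_log_likelihood(rs$histories, rs$design, rs$beta)),
      1e-10
    )
  }
})

test_that("censoring is neutral to post-censoring days", {
  # appending days after a censored nest's last observation and
  # re-censoring gives an identical likelihood
  nests <- toy_nests(1)
  nests$lay_day <- 0L; nests$end_day <- 10L; nests$fate <- "predated"
  design <- tidyr::expand_grid(nests[, c("nest_id", "year")], t = 1:26)
  design$Intercept <- 1
  design$NestAge <- age_scaled(design$t)
  beta <- c(Intercept = 2.5, NestAge = -0.5)
  h1 <- encode_histories(cap_activity(nests), "no_predation")
  nests2 <- nests
  nests2$end_day <- 10L  # same censoring day regardless of later fate
  h2 <- encode_histories(cap_activity(nests2), "no_predation")
  expect_equal(scenario_log_likelihood(h1, design, beta),
               scenario_log_likelihood(h2, design, beta))
})

test_that("the split-chain Gelman-Rubin statistic behaves", {
  # 4 chains of iid draws from one normal: converged
  set.seed(91)
  draws <- array(rnorm(4000), dim = c(1000, 4, 1),
                 dimnames = list(NULL, NULL, "theta"))
  expect_lt(gelman_rubin(draws)["theta"], 1.05)

  # chains centred 10 apart: far above the 1.10 gate
  bad <- array(c(rnorm(1000, 0), rnorm(1000, 10)), dim = c(1000, 2, 1))
  expect_gt(gelman_rubin(bad)[1], 2)

  # identical short chains: B = 0 branch of the documented formula,
  # R-hat = sqrt((n - 1) / n)
  expect_equal(unname(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3)))),
               sqrt(2 / 3))

  expect_error(gelman_rubin(array(rnorm(10), dim = c(10, 1, 1))),
               "two chains")
})

test_that("effects are clear when the 95% CrI excludes zero", {
  # posterior shapes mirroring reported coefficient rows (mean, SD);
  # deterministic normal grids so the empirical quantiles are exact
  ng <- function(m, s) qnorm(ppoints(20000), m, s)
  draws <- cbind(
    Nests = ng(3.20, 0.33),   # CrI ~ [2.55, 3.85]: clear
    Leks = ng(0.05, 0.11),    # CrI ~ [-0.17, 0.27]: not clear
    Edges = ng(-0.41, 0.215)  # CrI ~ [-0.83, 0.01]: barely overlaps zero
  )
  cls <- classify_effects(draws)
  expect_equal(cls$clear, c(TRUE, FALSE, FALSE))
  expect_equal(cls$lower[1], qnorm(0.025, 3.20, 0.33), tolerance = 1e-3)
  # all-negative draws are clear too
  cls2 <- classify_effects(cbind(NestAge = ng(-0.88, 0.11)))
  expect_true(cls2$clear)
})

test_that("the MLE oracle recovers closed forms and flags degeneracies", {
  # 100 exposure days with 5 failures: S-hat = 0.95
  nests <- toy_nests(5)
  nests$lay_day <- 0L
  nests$end_day <- 20L
  nests$fate <- c("predated", "predated", "predated", "predated", "predated")
  h <- encode_histories(cap_activity(nests), "overall")
  design <- tidyr::expand_grid(nests[, c("nest_id", "year")], t = 1:26)
  design$Intercept <- 1
  m <- mle_oracle_fit(h, design, coef_names = "Intercept")
  expect_equal(plogis(m$estimate), 0.95, tolerance = 1e-4)

  # zero failures: boundary flagged
  nests$fate <- "hatched"; nests$end_day <- 26L
  h0 <- encode_histories(cap_activity(nests), "overall")
  expect_warning(m0 <- mle_oracle_fit(h0, design, coef_names = "Intercept"),
                 "boundary|separation")
  expect_true(attr(m0, "separation"))
})

test_that("the MLE oracle matches glm and recovers truth at scale", {
  # ~10,000 nest-days simulated from known coefficients
  cfg <- recovery_config(rng_seed = 77, incubated_fraction = 0.2)
  st <- simulate_nest_study(cfg)
  h <- encode_histories(cap_activity(st$nests), "overall", "all_nests")
  d <- dsr_design(st$covariates, "all_nests")
  expect_gt(nrow(h), 3000)
  m <- mle_oracle_fit(h, d)

  # independent route: logistic regression on the nest-day records
  dat <- dplyr::inner_join(h, d, by = c("nest_id", "year", "t"))
  X <- as.matrix(dat[, m$term])
  g <- stats::glm.fit(X, dat$y, family = stats::binomial())
  expect_equal(m$estimate, unname(g$coefficients), tolerance = 1e-4)

  # estimates near truth (no year effect in the oracle, so allow its
  # displacement on top of 3 SE)
  se <- sqrt(diag(solve(crossprod(X * sqrt(g$weights)))))
  truth <- cfg$true_params$beta[m$term]
  z <- abs(m$estimate - truth) / se
  expect_true(all(z[!(m$term %in% "Intercept")] < 3.5))
})

test_that("the posterior matches the MLE for an intercept-only model", {
  set.seed(83)
  n <- 80
  nests <- toy_nests(n)
  nests$nest_id <- sprintf("n%03d", seq_len(n))
  nests$end_day <- pmin(26L, rgeom(n, 0.05) + 1L)
  nests$fate <- ifelse(nests$end_day >= 26L, "hatched", "predated")
  h <- encode_histories(cap_activity(nests), "overall")
  design <- tidyr::expand_grid(nests[, c("nest_id", "year")], t = 1:26)
  design$Intercept <- 1
  spec <- dsr_model_spec(chains = 4, iterations = 1500, warmup = 750,
                         year_effect = FALSE, rng_seed = 2)
  fit <- sample_posterior(h, design, spec)
  s_mle <- 1 - sum(h$y == 0) / nrow(h)
  s_post <- plogis(ruffsurv:::draws_matrix(fit)[, "Intercept"])
  mc_se <- sd(s_post) / sqrt(400)  # conservative effective draw count
  expect_lt(abs(mean(s_post) - s_mle), max(2 * mc_se, 0.004))
  expect_lt(max(fit$rhat), 1.05)
})

test_that("posterior sampling is exactly reproducible under a seed", {
  fit <- cached_recovery_fit()
  cfg <- recovery_config(rng_seed = 31, n_years = 2, nests_per_year = 60,
                         years = 2018:2019)
  st <- simulate_nest_study(cfg)
  h <- encode_histories(cap_activity(st$nests), "overall", "all_nests")
  d <- dsr_design(st$covariates, "all_nests")
  fit2 <- suppressWarnings(sample_posterior(
    h, d, dsr_model_spec(chains = 4, iterations = 800, warmup = 400,
                         rng_seed = 5)))
  expect_identical(fit$draws, fit2$draws)
  # a different seed moves the draws
  fit3 <- suppressWarnings(sample_posterior(
    h, d, dsr_model_spec(chains = 4, iterations = 800, warmup = 400,
                         rng_seed = 6)))
  expect_false(identical(fit$draws, fit3$draws))
  # post-warmup draw count is chains x (iterations - warmup)
  expect_equal(dim(fit$draws)[1] * dim(fit$draws)[2], 4 * 400)
})

test_that("with no annual variation the posterior matches the fixed-effect MLE", {
  cfg <- recovery_config(
    rng_seed = 97, incubated_fraction = 0,
    true_params = true_parameters(sigma_year = 0,
                                  flood_lethality = 0, trampling_hazard = 0,
                                  abandonment_hazard = 0)
  )
  st <- simulate_nest_study(cfg)
  h <- encode_histories(cap_activity(st$nests), "overall", "all_nests")
  d <- dsr_design(st$covariates, "all_nests")
  d$Incubation <- NULL  # constant column: drop rather than sample its prior
  fit <- suppressWarnings(sample_posterior(
    h, d, dsr_model_spec(chains = 4, iterations = 1500, warmup = 750,
                         rng_seed = 11)))
  s <- posterior_summary_table(fit)
  # sigma posterior concentrates near zero
  expect_lt(s$mean[s$term == "SigmaYear"], 0.6)
  m <- mle_oracle_fit(h, d)
  for (nm in c("Nests", "Q.Nests", "NestAge")) {
    expect_lt(abs(s$mean[s$term == nm] - m$estimate[m$term == nm]), 0.1)
  }
})

test_that("fit accessors expose tidy summaries", {
  fit <- cached_recovery_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high", "rhat", "clear") %in% names(td)))
  expect_true("SigmaYear" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$chains, 4L)
  expect_equal(gl$draws, 1600)
  expect_equal(gl$n_nests, fit$n_nests)
})
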