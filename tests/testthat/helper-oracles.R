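# Brute-force oracles and small fixtures shared across tests. Every oracle
# here is deliberately naive and independent of the package's
# implementation path.

# Distance from a point to a polyline by dense sampling of every segment.
bf_polyline_distance <- function(p, polyline, n_samples = 20000) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    tt <- seq(0, 1, length.out = n_samples)
    qx <- a[1] + tt * (b[1] - a[1]); qy <- a[2] + tt * (b[2] - a[2])
    best <- min(best, sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2)))
  }
  best
}

# Winding-number point-in-polygon test (polygon as closed coordinate matrix).
bf_point_in_polygon <- function(p, poly) {
  wn <- 0
  n <- nrow(poly)
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    if (a[2] <= p[2]) {
      if (b[2] > p[2] &&
          (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2]) > 0) {
        wn <- wn + 1
      }
    } else if (b[2] <= p[2] &&
               (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2]) < 0) {
      wn <- wn - 1
    }
  }
  wn != 0
}

# Per-day brute-force mean daily nearest-active-neighbour distance.
bf_daily_nn <- function(nests, i) {
  vals <- c()
  for (d in nests$lay_day[i]:nests$end_day[i]) {
    dists <- c()
    for (j in seq_len(nrow(nests))) {
      if (j == i || nests$year[j] != nests$year[i]) next
      if (nests$lay_day[j] <= d && d <= nests$end_day[j]) {
        dists <- c(dists, sqrt((nests$x[i] - nests$x[j])^2 +
                                 (nests$y[i] - nests$y[j])^2))
      }
    }
    if (length(dists) > 0) vals <- c(vals, min(dists))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Brute-force Bernoulli chain log-likelihood: walk each nest's history
# day by day and multiply the per-day probabilities.
bf_log_likelihood <- function(histories, design, beta, year_effects = NULL) {
  total <- 0
  for (id in unique(histories$nest_id)) {
    h <- histories[histories$nest_id == id, ]
    h <- h[order(h$t), ]
    for (r in seq_len(nrow(h))) {
      drow <- design[design$nest_id == id & design$t == h$t[r], ]
      eta <- 0
      for (nm in names(beta)) eta <- eta + beta[[nm]] * drow[[nm]]
      if (!is.null(year_effects)) {
        eta <- eta + year_effects[[as.character(drow$year)]]
      }
      s <- 1 / (1 + exp(-eta))
      total <- total + if (h$y[r] == 1) log(s) else log(1 - s)
    }
  }
  total
}

# Minimal hand-made nest table; fates/protection filled by callers.
toy_nests <- function(n = 4, year = 2018L) {
  tibble::tibble(
    nest_id = sprintf("t%02d", seq_len(n)), year = year,
    x = seq(0, by = 100, length.out = n), y = rep(500, n),
    lay_day = 0L, end_day = 26L, fate = "hatched", clutch_size = 4L,
    protected_cause = "none", intervention_day = NA_integer_,
    artificially_incubated = FALSE
  )
}

# Random small encoded dataset with matching intercept+age design, for
# likelihood oracle checks.
random_history_set <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  nests <- toy_nests(n)
  nests$lay_day <- sample(0:5, n, replace = TRUE)
  exposure <- sample(1:8, n, replace = TRUE)
  nests$end_day <- nests$lay_day + exposure
  nests$fate <- sample(c("hatched", "predated", "flooded", "unknown"),
                       n, replace = TRUE)
  nests$end_day[nests$fate == "hatched"] <- nests$lay_day[nests$fate == "hatched"] + 26L
  h <- encode_histories(cap_activity(nests), sample(
    c("overall", "no_predation", "predation"), 1))
  design <- tidyr::expand_grid(nests[, c("nest_id", "year")], t = 1:26)
  design$Intercept <- 1
  design$NestAge <- age_scaled(design$t)
  beta <- c(Intercept = rnorm(1, 2, 0.5), NestAge = rnorm(1, 0, 0.5))
  list(histories = h, design = design, beta = beta)
}

# A tiny fitted model on simulated data, cached per session for the
# report-module tests.
cached_recovery_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- recovery_config(rng_seed = 31, n_years = 2,
                             nests_per_year = 60, years = 2018:2019)
      st <- simulate_nest_study(cfg)
      h <- encode_histories(cap_activity(st$nests), "overall", "all_nests")
      d <- dsr_design(st$covariates, "all_nests")
      val <<- suppressWarnings(sample_posterior(
        h, d, dsr_model_spec(chains = 4, iterations = 800, warmup = 400,
                             rng_seed = 5)))
    }
    val
  }
})
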