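#' Daily survival probability from the logit model
#'
#' Inverse-logit of the linear predictor
#' `beta0 + beta'x + beta_age * age + year_effect`, where `x` are the
#' within-year scaled covariates and `age` the scaled day index.
#'
#' @param covariates Named numeric vector (or single-row data frame) of
#'   scaled covariate values; names must match coefficient names (the
#'   intercept is added automatically and missing covariates count as 0,
#'   the scaled mean).
#' @param age_t Scaled nest-age value(s); use [age_scaled()] to convert a
#'   raw day index.
#' @param coefficients Named coefficient vector (see [true_parameters()]
#'   for the naming).
#' @param year_effect Year random-effect contribution on the logit scale
#'   (default 0).
#' @return Daily survival probability in (0, 1); vectorised over `age_t`.
#' @export
#' @examples
#' b <- c(Intercept = 3, NestAge = -1)
#' daily_survival_probability(c(), age_t = 0, coefficients = b)    # 0.95257
#' daily_survival_probability(c(), age_t = 1, coefficients = b)    # 0.88080
daily_survival_probability <- function(covariates, age_t, coefficients,
                                       year_effect = 0) {
  if (is.data.frame(covariates)) covariates <- unlist(covariates[1, ])
  eta <- unname(coefficients["Intercept"] %||% 0)
  if (is.na(eta)) eta <- 0
  for (nm in names(covariates)) {
    if (nm %in% names(coefficients)) {
      eta <- eta + coefficients[[nm]] * covariates[[nm]]
    }
  }
  age_beta <- if ("NestAge" %in% names(coefficients)) coefficients[["NestAge"]] else 0
  out <- eta + age_beta * age_t + year_effect
  if (any(!is.finite(out))) {
    stop("non-finite linear predictor", call. = FALSE)
  }
  inv_logit(out)
}

#' Scaled nest age
#'
#' The nest-age covariate is the transition-day index `t` (1..26) scaled by
#' the fixed mean and sample standard deviation of the 26-day window, so the
#' covariate does not depend on which nest-days happen to be observed.
#'
#' @param t Day index (0..26).
#' @return Scaled age value(s).
#' @export
age_scaled <- function(t) age_scale(t)

#' Log-likelihood of encoded histories
#'
#' The Bernoulli exposure-day likelihood: every survived transition
#' contributes `log(S_it)` and every terminal failure `log(1 - S_iT)`;
#' censored histories contribute only survival terms. `S_it` comes from the
#' linear predictor of the design row matched by `nest_id` and `t`.
#'
#' @param histories Long history tibble from [encode_histories()].
#' @param design Nest-day design tibble from [dsr_design()].
#' @param beta Named coefficient vector (names matching design columns).
#' @param year_effects Optional named vector (by year) of logit-scale year
#'   contributions (`sigma_year * u_year`); default all 0.
#' @return The log-likelihood (scalar). `-Inf` if an observed transition has
#'   probability exactly 0 or 1 against it.
#' @export
scenario_log_likelihood <- function(histories, design, beta,
                                    year_effects = NULL) {
  stopifnot(all(is.finite(beta)))
  dat <- dplyr::inner_join(histories, design, by = c("nest_id", "year", "t"))
  if (nrow(dat) != nrow(histories)) {
    stop("design rows missing for some history rows", call. = FALSE)
  }
  nm <- intersect(names(beta), names(dat))
  X <- as.matrix(dat[, nm])
  eta <- as.numeric(X %*% beta[nm])
  if (!is.null(year_effects)) {
    eta <- eta + unname(year_effects[as.character(dat$year)])
  }
  S <- inv_logit(eta)
  ll <- sum(log(S[dat$y == 1L])) + sum(log(1 - S[dat$y == 0L]))
  ll
}

#' Model specification: priors, chains, iterations
#'
#' Prior classes: Gaussian (mean 0, SD 2) on the continuous fixed effects
#' (intercept included), standard Gaussian on the year deviates, Cauchy
#' (location 0, scale 2) on the categorical incubation effect and a
#' half-Cauchy (scale 5) on the year standard deviation. Sampling runs 4
#' chains of 5000 iterations, discarding 2500 as warmup; convergence is
#' flagged at a potential scale reduction factor of 1.10.
#'
#' @param scenario,variant Mortality scenario and dataset variant labels.
#' @param chains Number of chains (>= 2).
#' @param iterations Iterations per chain (warmup included).
#' @param warmup Warmup iterations discarded per chain.
#' @param rhat_threshold Convergence gate on the Gelman-Rubin statistic.
#' @param year_effect Include the year random effect (`FALSE` drops it,
#'   e.g. for single-year or intercept-only checks).
#' @param target_accept Acceptance target of the step-size adaptation.
#' @param rng_seed Integer seed; fixes the posterior draws exactly.
#' @return A list of class `"dsr_model_spec"`.
#' @export
dsr_model_spec <- function(scenario = "overall", variant = "all_nests",
                           chains = 4, iterations = 5000, warmup = 2500,
                           rhat_threshold = 1.10, year_effect = TRUE,
                           target_accept = 0.8, rng_seed = 1L) {
  stopifnot(chains >= 2, warmup < iterations, warmup >= 1)
  structure(
    list(
      scenario = check_scenario(scenario), variant = check_variant(variant),
      chains = as.integer(chains), iterations = as.integer(iterations),
      warmup = as.integer(warmup), rhat_threshold = rhat_threshold,
      year_effect = isTRUE(year_effect), target_accept = target_accept,
      rng_seed = as.integer(rng_seed)
    ),
    class = "dsr_model_spec"
  )
}

#' Sample the posterior of the daily survival model
#'
#' Fits the hierarchical Bernoulli exposure-day model by Hamiltonian Monte
#' Carlo. Reported parameters are the fixed-effect coefficients, the year
#' standard deviation `SigmaYear` and the per-year effects
#' (`sigma_year * u_year`, the model's year rows). A convergence report
#' (split-chain Gelman-Rubin statistics, acceptance rates, divergences) is
#' attached; parameters at or above the threshold are flagged with a
#' warning.
#'
#' @param histories Long history tibble from [encode_histories()].
#' @param design Nest-day design from [dsr_design()].
#' @param spec A [dsr_model_spec()].
#' @return An object of class `"dsr_fit"`: list with `draws` (array
#'   iterations x chains x parameters with dimnames), `rhat`, `accept`,
#'   `divergences`, `spec`, `scaling`, `years`, and data summaries.
#' @export
sample_posterior <- function(histories, design, spec = dsr_model_spec()) {
  stopifnot(inherits(spec, "dsr_model_spec"))
  dat <- dplyr::inner_join(histories, design, by = c("nest_id", "year", "t"))
  if (nrow(dat) != nrow(histories)) {
    stop("design rows missing for some history rows", call. = FALSE)
  }
  coef_nm <- intersect(coef_names_for_variant(spec$variant), names(dat))
  X <- as.matrix(dat[, coef_nm])
  y <- as.numeric(dat$y)
  n_fail <- sum(y == 0)
  if (n_fail == 0) {
    warning("no failure events in the data; the intercept is only weakly ",
            "identified")
  }
  years <- sort(unique(dat$year))
  G <- if (spec$year_effect) length(years) else 0L
  yridx <- if (G > 0) match(dat$year, years) else integer(0)
  cauchy_idx <- match("Incubation", coef_nm) - 1L
  if (is.na(cauchy_idx)) cauchy_idx <- -1L

  res <- hmc_sampler(X, y, as.integer(yridx), G, cauchy_idx,
                     spec$chains, spec$iterations, spec$warmup,
                     spec$target_accept, spec$rng_seed)
  par_names <- c(coef_nm,
                 if (G > 0) c("SigmaYear", paste("Year", years)))
  draws <- res$draws
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(spec$chains)),
                          par_names)
  rhat <- gelman_rubin(draws)
  fit <- structure(
    list(
      draws = draws, par_names = par_names, rhat = rhat,
      accept = as.numeric(res$accept),
      divergences = as.integer(res$divergences),
      step_size = as.numeric(res$step_size),
      spec = spec, years = years,
      scaling = attr(design, "scaling"),
      raw_ranges = attr(design, "raw_ranges"),
      n_nests = length(unique(dat$nest_id)),
      n_exposure_days = nrow(dat), n_failures = n_fail
    ),
    class = "dsr_fit"
  )
  flagged <- names(rhat)[rhat >= spec$rhat_threshold]
  if (length(flagged) > 0) {
    warning("R-hat at or above ", spec$rhat_threshold, " for: ",
            paste(flagged, collapse = ", "))
  }
  fit
}

#' Fit the daily survival model from nest records
#'
#' High-level wrapper: computes distance covariates (unless supplied),
#' scales them within year, encodes histories for the requested scenario
#' and variant, and samples the posterior.
#'
#' @param nests Nest tibble (fates assigned).
#' @param landscape The landscape (needed unless `covariates` is given).
#' @param spec A [dsr_model_spec()]; its `scenario`/`variant` select the
#'   encoding.
#' @param covariates Optional pre-built [dsr_covariates()] table.
#' @return A `"dsr_fit"`.
#' @export
fit_dsr <- function(nests, landscape = NULL, spec = dsr_model_spec(),
                    covariates = NULL) {
  nests <- cap_activity(nests)
  if (is.null(covariates)) {
    stopifnot(!is.null(landscape))
    covariates <- dsr_covariates(nest_distances(nests, landscape))
  }
  histories <- encode_histories(nests, spec$scenario, spec$variant)
  design <- dsr_design(covariates, spec$variant)
  sample_posterior(histories, design, spec)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain variant: every chain of length >= 4 is split into its first
#' and last halves (the middle draw is dropped for odd lengths); shorter
#' chains are used unsplit. With `m` resulting sequences of length `n`,
#' within-chain variance `W` is the mean of the sequence variances, the
#' between term is `B = n * Var(sequence means)`, the pooled variance is
#' `V = (n - 1)/n * W + B/n`, and `R-hat = sqrt(V / W)`. Identical chains
#' give `B = 0` and `R-hat = sqrt((n - 1)/n)`.
#'
#' @param draws Array `iterations x chains x parameters` (a matrix is
#'   treated as one parameter), or a list of equal-length chain vectors.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(1, 2, 3)))  # B = 0 branch
gelman_rubin <- function(draws) {
  if (is.list(draws) && !is.array(draws)) {
    draws <- array(unlist(draws), dim = c(length(draws[[1]]), length(draws), 1))
  }
  if (length(dim(draws)) == 2) {
    draws <- array(draws, dim = c(dim(draws), 1),
                   dimnames = c(dimnames(draws), list(NULL)))
  }
  n_iter <- dim(draws)[1]; n_chain <- dim(draws)[2]; n_par <- dim(draws)[3]
  if (n_chain < 2) {
    stop("at least two chains are required", call. = FALSE)
  }
  out <- numeric(n_par)
  for (k in seq_len(n_par)) {
    if (n_iter >= 4) {
      h <- n_iter %/% 2L
      seqs <- c(
        lapply(seq_len(n_chain), function(c) draws[seq_len(h), c, k]),
        lapply(seq_len(n_chain), function(c) {
          draws[seq(n_iter - h + 1L, n_iter), c, k]
        })
      )
    } else {
      seqs <- lapply(seq_len(n_chain), function(c) draws[, c, k])
    }
    n <- length(seqs[[1]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    V <- (n - 1) / n * W + B / n
    out[k] <- if (W > 0) sqrt(V / W) else 1
  }
  names(out) <- dimnames(draws)[[3]]
  out
}

#' Classify effects by their 95% credible interval
#'
#' A predictor has a clear effect when the central 95% credible interval of
#' its coefficient excludes zero (2.5% and 97.5% quantiles share a sign).
#'
#' @param draws A `"dsr_fit"`, or a draws matrix/array with named
#'   parameters.
#' @return Tibble with `term`, `lower`, `upper` (95% CrI) and `clear`.
#' @export
classify_effects <- function(draws) {
  m <- draws_matrix(draws)
  q <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = colnames(m), lower = unname(q[1, ]), upper = unname(q[2, ]),
    clear = unname(sign(q[1, ]) == sign(q[2, ]) & q[1, ] != 0)
  )
}

# Flatten fit/array/matrix draws into draws x parameters.
draws_matrix <- function(draws) {
  if (inherits(draws, "dsr_fit")) draws <- draws$draws
  if (is.array(draws) && length(dim(draws)) == 3) {
    d <- dim(draws)
    m <- matrix(aperm(draws, c(1, 2, 3)), d[1] * d[2], d[3])
    colnames(m) <- dimnames(draws)[[3]]
    m
  } else {
    as.matrix(draws)
  }
}

#' Maximum-likelihood oracle fit (no random effects)
#'
#' Maximises the exposure-day log-likelihood over the fixed-effect
#' coefficients by numerical optimisation (L-BFGS-B, coefficients bounded
#' at +-15). Used as an independent check of the posterior's location on
#' large datasets; it has no year effect.
#'
#' @inheritParams scenario_log_likelihood
#' @param coef_names Coefficients to estimate (default: all design columns
#'   that are model coefficients).
#' @return Tibble with `term` and `estimate`; attributes `logLik`,
#'   `convergence` and `separation` (any estimate at the bound or beyond
#'   10 in magnitude triggers a warning and the flag).
#' @export
mle_oracle_fit <- function(histories, design, coef_names = NULL) {
  if (is.null(coef_names)) {
    coef_names <- intersect(COEF_NAMES, names(design))
  }
  dat <- dplyr::inner_join(histories, design, by = c("nest_id", "year", "t"))
  X <- as.matrix(dat[, coef_names])
  y <- as.numeric(dat$y)
  # numerically stable negative log-likelihood and gradient
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    l1pe <- ifelse(eta > 35, eta, log1p(exp(pmin(eta, 35))))
    -sum(y * eta - l1pe)
  }
  gr <- function(b) {
    eta <- as.numeric(X %*% b)
    -as.numeric(crossprod(X, y - inv_logit(eta)))
  }
  start <- rep(0, length(coef_names))
  names(start) <- coef_names
  opt <- stats::optim(start, nll, gr, method = "L-BFGS-B",
                      lower = -15, upper = 15,
                      control = list(maxit = 500))
  est <- opt$par
  sep <- any(abs(est) >= 10)
  if (sum(y == 0) == 0) {
    sep <- TRUE
    warning("no failures: survival estimate at the boundary")
  } else if (sep) {
    warning("possible separation: estimate(s) bounded at large magnitude")
  }
  out <- tibble::tibble(term = coef_names, estimate = unname(est))
  attr(out, "logLik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  attr(out, "separation") <- sep
  out
}

#' @export
print.dsr_fit <- function(x, ...) {
  cat(sprintf("<dsr_fit> scenario '%s', variant '%s'\n",
              x$spec$scenario, x$spec$variant))
  cat(sprintf("  %d nests, %d exposure days, %d failures\n",
              x$n_nests, x$n_exposure_days, x$n_failures))
  cat(sprintf("  %d chains x %d iterations (%d warmup); max R-hat %.3f; %d divergence(s)\n",
              x$spec$chains, x$spec$iterations, x$spec$warmup,
              max(x$rhat), sum(x$divergences)))
  print(posterior_summary_table(x), n = Inf)
  invisible(x)
}

#' @export
tidy.dsr_fit <- function(x, ...) {
  s <- posterior_summary_table(x)
  tibble::tibble(
    term = s$term, estimate = s$mean, std.error = s$sd,
    conf.low = s$cri_lower, conf.high = s$cri_upper,
    rhat = unname(x$rhat[s$term]), clear = s$clear
  )
}

#' @export
glance.dsr_fit <- function(x, ...) {
  tibble::tibble(
    scenario = x$spec$scenario, variant = x$spec$variant,
    n_nests = x$n_nests, n_exposure_days = x$n_exposure_days,
    n_failures = x$n_failures, chains = x$spec$chains,
    draws = dim(x$draws)[1] * dim(x$draws)[2],
    max_rhat = max(x$rhat), divergences = sum(x$divergences),
    converged = max(x$rhat) < x$spec$rhat_threshold
  )
}
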