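# ruffsurv

Daily nest survival analysis for ruffs (*Calidris pugnax*) breeding on
grazed coastal meadows — and for anyone modelling known-fate nest survival
with competing mortality causes, spatial covariates and a clutch-protection
intervention.

Ground nests on managed shore meadows fail from predation, storm-surge
flooding, cattle trampling and abandonment. `ruffsurv` packages the whole
analysis chain for such a study: a seeded synthetic-data generator (so every
stage is testable without field data), spatial covariate construction,
censoring/encoding of nest histories under cause-specific scenarios, a
hierarchical Bayesian daily-survival model with its own Hamiltonian Monte
Carlo sampler, and reporting utilities.

## The model

A nest is active from its lay day ($t = 0$) through at most 26 daily
transitions. Daily survival follows a Bernoulli chain
$y_{i,t} \sim \mathrm{Bernoulli}(y_{i,t-1} S_{i,t})$ with

$$\operatorname{logit} S_{i,t} = \beta_0
  + \beta_1 \mathrm{nests}_i + \beta_2 \mathrm{nests}_i^2
  + \beta_3 \mathrm{leks}_i + \beta_4 \mathrm{leks}_i^2
  + \beta_5 \mathrm{laydate}_i + \beta_6 \mathrm{age}_t
  + \beta_7 \mathrm{incubation}_i
  + \beta_8 \mathrm{paths}_i + \beta_9 \mathrm{edge}_i
  + \beta_{10} \mathrm{shore}_i
  + \sigma_{\mathrm{year}}\, u_{\mathrm{year}(i)},$$

where all covariates are centred and scaled within year, nest age is the
scaled day index, incubation flags clutches artificially incubated > 24 h,
and year enters as a random intercept. Priors: Gaussian(0, 2) on continuous
fixed effects, N(0, 1) on year deviates, Cauchy(0, 2) on the categorical
incubation effect, half-Cauchy(0, 5) on $\sigma_{\mathrm{year}}$. Sampling:
4 chains × 5000 iterations (2500 warmup), convergence gated at
Gelman–Rubin $\widehat R < 1.10$; an effect is *clear* when its 95%
credible interval excludes zero.

Three mortality scenarios re-encode the same records — **overall** (all
deaths are failures), **no_predation** (predated nests censored) and
**predation** (only predated nests are failures) — crossed with two dataset
variants: **all_nests** (realized fates) and **natural_only** (fates
truncated at human intervention). See the methods vignette
(`vignettes/daily-nest-survival.Rmd`) for every convention and its
rationale.

## Worked example

Simulate a six-season study (275 nests, floods, cattle, protection policy),
summarise fates, and fit the Overall model:

```r
library(ruffsurv)

cfg   <- scenario_config(rng_seed = 42)
study <- simulate_nest_study(cfg)
study
#> <ruff_study>
#>   275 nests over 6 years; fates: abandoned=23, escaped=2, flooded=19,
#>     hatched=128, predated=79, trampled=14, unknown=2, unknown_dead=8
#>   39 protected nest(s) (32 artificially incubated > 24 h)

nests <- cap_activity(study$nests)
fate_summary_table(nests, "all_nests") |> dplyr::filter(year == "all")
#>   year      n n_hatched pct_hatched n_failed pct_predated pct_flooded ...
#> 1 all     271       128        47.2      143         55.2        13.3 ...
```

47.2% of fate-known nests hatched; predation accounts for 55.2% of the 143
failures. Distance covariates and the model fit:

```r
fit <- fit_dsr(nests, study$landscape,
               dsr_model_spec(scenario = "overall", variant = "all_nests",
                              chains = 4, iterations = 2000, warmup = 1000,
                              rng_seed = 1))
tidy(fit)
#>   term      estimate std.error conf.low conf.high  rhat clear
#> 1 Intercept   3.76      0.317     3.08     4.37    1.03 TRUE
#> 2 Nests       0.987     0.218     0.595    1.44    1.02 TRUE
#> 3 Q.Nests    -0.314     0.0604   -0.432   -0.196   1.02 TRUE
#> 4 Leks       -0.141     0.112    -0.355    0.0827  1.02 FALSE
#> ...
```

The positive linear and negative quadratic nearest-nest terms are clear:
daily survival peaks at intermediate distances to other nests. The
intercept (3.76 on the logit scale) puts daily survival at the covariate
means near 0.977, and multiplying the posterior-mean daily survival over
the 26-day window,

```r
cumulative_hatch_probability(dsr_prediction_curve(fit, "NestAge")$mean)
#> [1] 0.514
```

gives a laying-to-hatching success probability of about 0.51 for an
average nest in an average year. `autoplot(fit)` draws the
coefficient-interval panel; `autoplot(dsr_prediction_curve(fit, "Nests"))`
draws a survival curve with 80%/95% bands.

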