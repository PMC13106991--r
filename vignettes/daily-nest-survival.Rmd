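---
title: "Daily nest survival of ruffs on grazed coastal meadows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily nest survival of ruffs on grazed coastal meadows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruffsurv)
```

## The problem

Ground-nesting waders on managed coastal meadows lose nests to several
competing causes: predation, storm-surge flooding, trampling by grazing
cattle, and abandonment. For ruffs (*Calidris pugnax*), where females
(reeves) nest in loose aggregations around male display sites (leks), the
social and spatial placement of a nest — how far it sits from other nests,
from leks, from the shoreline, the meadow edge and from paths — may shape
its daily survival probability. A conservation intervention swaps high-risk
clutches for plastic dummy eggs and incubates the real eggs artificially,
which changes both the nest's exposure to its threatened cause and its
attractiveness to predators.

`ruffsurv` implements the full analysis pipeline for this setting:

1. a **synthetic-data generator** that simulates multi-season nest studies
   with all four mortality causes and the protection intervention;
2. **spatial covariate construction** (five distance covariates);
3. **encoding** of nest records into daily Bernoulli survival histories
   under three mortality scenarios and two dataset variants;
4. a **hierarchical Bayesian daily-survival model** fitted by Hamiltonian
   Monte Carlo, with convergence diagnostics and a maximum-likelihood
   cross-check;
5. **reporting**: fate tables, posterior summaries, survival prediction
   curves and cumulative hatch probabilities.

## The survival model

A nest is active from its lay day (day $t = 0$, alive by definition)
through at most 26 daily transitions. Its status
$y_{i,t} \in \{0, 1\}$ follows a conditional Bernoulli chain,

$$y_{i,t} \sim \mathrm{Bernoulli}(y_{i,t-1}\, S_{i,t}),$$

so an active nest survives day $t$ with the daily survival rate (DSR)

$$\operatorname{logit} S_{i,t} = \beta_0
  + \beta_1 \mathrm{nests}_i + \beta_2 \mathrm{nests}_i^2
  + \beta_3 \mathrm{leks}_i + \beta_4 \mathrm{leks}_i^2
  + \beta_5 \mathrm{laydate}_i + \beta_6 \mathrm{age}_t
  + \beta_7 \mathrm{incubation}_i
  + \beta_8 \mathrm{paths}_i + \beta_9 \mathrm{edge}_i
  + \beta_{10} \mathrm{shore}_i
  + \sigma_{\mathrm{year}} u_{\mathrm{year}(i)}.$$

Every survived transition contributes $\log S_{i,t}$ to the likelihood and
a terminal failure contributes $\log(1 - S_{i,T})$; censored nests
contribute survival terms only (`scenario_log_likelihood()`). The year
effect is a random intercept with standard-normal deviates $u$ scaled by
$\sigma_{\mathrm{year}}$.

Priors follow the class of each term: Gaussian (mean 0, SD 2) on the
continuous fixed effects, standard Gaussian on the year deviates, Cauchy
(location 0, scale 2) on the categorical incubation effect, and a
half-Cauchy (scale 5) on $\sigma_{\mathrm{year}}$. The intercept is treated
as a continuous fixed effect (Gaussian, SD 2); the prior classes do not
single it out, and with several hundred exposure days its likelihood
information dominates. The sigma prior is read as the standard half-Cauchy
scale prior, i.e. a Cauchy(0, 5) truncated at zero.

Effects are called **clear** when the central 95% credible interval of the
coefficient excludes zero (`classify_effects()`).

### Scenarios and variants

Cause-specific questions are asked by re-encoding the same records
(`encode_histories()`):

* **overall** — all deaths (predation, flooding, trampling, abandonment,
  and failures of unknown cause) are failures;
* **no_predation** — predated nests are censored on their failure date;
  flooded, trampled and abandoned nests are failures;
* **predation** — only predated nests are failures; other deaths are
  censored.

Deaths with evidence of failure but no attributable cause
(`unknown_dead`) are failures only in the overall scenario — the cause
cannot be assigned to either side of the split — and censored in both
cause-specific scenarios. Fully unknown and "escaped" fates (clutch
disappeared near term, probably hatched) are censored everywhere.

The two dataset variants differ in how protected nests are treated:

* **all_nests** keeps realized fates, with the artificial-incubation
  indicator (1 if the clutch spent more than 24 h in the incubator) as a
  fixed effect;
* **natural_only** discards post-intervention information: flood-protected
  clutches are recorded as flooded on the intervention day (the water
  would have reached them — this applies to short protections too), while
  trampling-protected clutches are censored on the intervention day,
  alive at their last observation, because trampling is an ongoing rather
  than a dated threat. This variant drops the incubation effect, since no
  post-intervention exposure remains.

### Timeline conventions

Lay dates are back-dated from observed or estimated hatch dates using a
21-day incubation period and a laying interval of 1.25 days per egg
(`estimate_timeline()`). The laying interval is applied over
`clutch_size - 1` inter-egg gaps — incubation starts at clutch completion,
and a 1-egg clutch starts incubating on its lay day — with rounding to the
nearest whole day. The alternative convention (multiplying by
`clutch_size`) shifts every lay date by roughly one day; the choice is
isolated in this one function.

Nest activity is capped at 26 days after laying (`cap_activity()`); longer
observed activity, typical of manipulated nests, is treated as having
survived the modelled window. A failure found on day $d$ enters the
likelihood on day $d$ exactly (no midpoint imputation); a nest censored at
a failure found on day $d$ was last known active on day $d - 1$, whereas a
nest censored at an intervention was alive on the intervention day itself.

Histories start at the (back-dated) lay day, not at discovery. Nests
destroyed before they could be found never enter a real dataset, so early
transitions are survivor-biased; the model reproduces the standard
construction and does not correct for this.

### Covariate scaling

Each distance covariate and the lay date are centred and scaled within
year (`scale_covariates_within_year()`): year-specific mean and sample SD,
so each season's covariates have mean 0 and SD 1. Quadratic terms are the
squares of the *scaled* linear terms (squaring before scaling makes the
linear and quadratic columns nearly collinear and the quadratic
coefficient uninterpretable).

Nest age is the transition-day index $t$, scaled by the fixed mean and
sample SD of the 1..26 window rather than by the realized nest-days. The
realized age distribution depends on the outcomes themselves (failed nests
contribute fewer old days), so outcome-dependent scaling would make the
covariate — and hence the age coefficient — a function of the data being
modelled; the fixed-window definition keeps the covariate meaning constant
across datasets and between a generative model and a fit to its output.

A nest that never had a concurrently active neighbour has an undefined
nearest-nest distance; its scaled value is set to 0, the year mean.

## Spatial covariates

All geometry is planar, in metres; at the kilometre scale of a coastal
meadow a projected planar frame is assumed and no geodesic corrections are
made. The five covariates (`nest_distances()`):

* **nests** — for every day the focal nest is active (closed interval from
  lay to end day), the distance to the nearest other nest of the same year
  active that day; averaged over days with at least one active neighbour.
  Days with no active neighbour are dropped, not imputed.
* **leks** — distance to the centre of the nearest lek active that year
  (the stored lek point; no polygon averaging).
* **shore**, **edge**, **paths** — nearest-point distance to the shoreline
  polyline, the meadow-edge polyline, and the closest of the path
  polylines (segment interiors and vertices both considered).

Pairwise Pearson correlations between the covariates, with two-sided
p-values on pairwise-complete observations, flag spatial redundancy before
modelling (`predictor_correlation_matrix()`).

## The synthetic-data generator

`simulate_nest_study()` generates a complete study from a
`scenario_config()`. The defaults describe the study conditions the
package is designed around: six seasons (2018–2023) totalling 275 nests on
a 3 km × 1.3 km meadow strip with the shoreline and the outer fence on
opposite sides, nine paths crossing it, twelve leks, three storm-surge
floods across the six seasons, cattle released around day 22 of the
season, and the protection policy active in four of the six seasons (in
one of which flood protections lasted a single day and therefore do not
count as artificial incubation).

Nests are placed by a lek-clustered hard-core process: most nests scatter
(SD 70 m) around a cluster centre displaced from an active lek (SD 250 m),
the rest are uniform over the nesting band, and no two same-year nests sit
within the inhibition radius (0.33 × the 121.2 m nearest-nest target
scale). Cluster members lay in loose synchrony (SD 3 days) around a
lek-specific base date — lek mating synchrony — which keeps neighbours
concurrently active and the *daily* nearest-nest distance close to the
static pattern scale. Clutches are 4 eggs with probability 0.8, else 3.

Fates are simulated by a daily walk over each nest's 26-day window. Causes
are resolved in a fixed order — flood, trampling, predation, abandonment —
and the first event wins:

* floods are dated events: on a flood day, unprotected active nests within
  the flood reach of the shoreline fail with lethality 0.9;
* after cattle release, unprotected nests inside the grazed zone face a
  daily trampling hazard (0.04);
* predation occurs with probability $1 - S_{i,t}$ from the survival model
  above, using the generating coefficients;
* abandonment has a constant daily hazard (0.005).

Floods are day-specific catastrophes, which is why they head the order;
the remaining order is immaterial at daily hazards of a few percent. The
protection policy designates nests with perfect foresight of the flood day
(mirroring protection on the forecast surge day) and swaps clutches in the
grazing area from three days before cattle release up to the release day.
From the intervention on, the natural clutch is immune to its protected
cause, and dummy-egg multipliers rescale the predation (×0.5, predators
discriminate dummies) and abandonment (×1.5, disturbance after nest-cup
damage) hazards.

The per-nest-day event draws are a function of the scenario seed only —
never of the policy — so runs with and without protection are coupled:
with all dummy-egg multipliers at or below 1, enabling the policy can only
increase the number of hatched nests. Everything downstream of the seed is
byte-level reproducible.

An observation layer relabels a small fraction of outcomes the way
fieldwork does: 6% of failures become `unknown_dead` (evidence of failure,
no attributable cause), 2% become fully `unknown`, and 1% of hatches
become `escaped`.

The generating coefficients default to an intercept of 4.6, a positive
linear (1.0) and negative quadratic (−0.4) nearest-nest-distance effect, a
negative age effect (−0.8), zeros elsewhere, and
$\sigma_{\mathrm{year}} = 0.5$. The cause-specific hazards are calibration
choices, not estimates — no field study quantifies them directly — chosen
once so that the default scenario reproduces the published fate and
distance scales of the motivating study system (roughly 45% of nests
hatching, predation slightly over half of failures, abandonment and
trampling next, mean daily nearest-nest distance near 120 m, path/edge/
shore distance means near 80/690/580 m, and protected cohorts of about a
dozen flood-protected and thirty-odd trampling-protected clutches). The
acceptance script recomputes these quantities end to end.

What the generator deliberately does **not** emulate: the nest discovery
process (histories start at lay, as in the model), renesting by the same
female, female identity (no female random effect in the model either),
between-year shoreline movement, weather beyond discrete flood days, and
brood survival after hatching. Two geometric simplifications matter when
reading simulated summaries: because the meadow is a straight strip, the
edge and shore distances are almost perfectly anti-correlated (real sites
are only partially opposing, giving correlations nearer −0.7), and because
nests cluster around displaced lek centres, mean lek distances come out
shorter (~170 m) than the field scale (~400 m). Passing tests on simulated
data therefore demonstrate the correctness of the machinery, not that the
model is well-specified for any particular field dataset.

### Parameter recovery

`recovery_config()` switches off every mortality cause except the
model-driven one (no floods, trampling, abandonment or fate-relabelling,
policy disabled) and flags 15% of nests as artificially incubated from
laying, so that all failures flow through the logit model and every
coefficient — including the incubation effect — is identified with a
well-defined truth. The test suite fits 20 replicate studies of 275 nests
× 6 years (4 chains × 1500 iterations each) and requires each
coefficient's 95% credible interval to cover its generating value in at
least 16 of 20 replicates. The recovery harness fits with the exact design
matrix the generative walk used (nearest-nest distances over potential
26-day windows): re-deriving that covariate from realized windows changes
the covariate itself, so "truth" would be undefined for that comparison.
Covariate construction is tested separately against brute-force oracles.

## Posterior computation

`sample_posterior()` fits the model by Hamiltonian Monte Carlo implemented
in C++ (RcppArmadillo): leapfrog trajectories of jittered length (about
one time unit), dual-averaging step-size adaptation targeting 80%
acceptance, and a dense mass matrix estimated from the warmup posterior
covariance — the meadow geometry makes several covariate pairs strongly
correlated, which a diagonal metric handles poorly. Divergent transitions
(energy error above 1000) are rejected and counted.

Internally the year effects are sampled on the centred scale
($v_g = \sigma u_g$ and $\log \sigma$): with several hundred exposure days
per year the per-year effects are strongly informed and the centred
geometry avoids the ridge that the non-centred parameterisation develops
in that regime. The model is identical — results are reported as
$\sigma_{\mathrm{year}}$ and the per-year composites $\sigma u_g$, the
model's year rows, with $u_g = v_g / \sigma$ available by division.

Defaults follow the standard protocol: 4 chains × 5000 iterations with
2500 discarded as warmup. Each chain derives its own `mt19937_64` stream
from the model seed, so draws are exactly reproducible. Tests and the
acceptance script use 1500–2000 iterations per chain — at ~4000 exposure
days the dense-metric sampler reaches split R-hat values near 1 well
within those sizes, and 20-replicate recovery studies complete in a couple
of minutes on one core.

Convergence is assessed with a split-chain Gelman–Rubin statistic
(`gelman_rubin()`): chains of length ≥ 4 are split into first and last
halves; with $m$ sequences of length $n$, $W$ = mean within-sequence
variance, $B = n \operatorname{Var}(\text{sequence means})$,
$\widehat V = \frac{n-1}{n} W + \frac{B}{n}$, and
$\widehat R = \sqrt{\widehat V / W}$. Values at or above 1.10 are flagged.
Identical chains give the $B = 0$ branch, $\widehat R = \sqrt{(n-1)/n}$.

`mle_oracle_fit()` provides an independent location check: it maximises
the same exposure-day likelihood over the fixed effects only (no year
effect) by L-BFGS-B with coefficients bounded at ±15; estimates at large
magnitude trigger a separation warning. On large simulated datasets the
posterior means should sit near these estimates, and with
$\sigma_{\mathrm{year}} = 0$ data the posteriors of the shared
coefficients match them closely.

## Reporting

`fate_summary_table()` gives hatch percentages and failure-cause shares
per year and pooled, under either variant's fate attribution; percentages
are rounded to one decimal place and recompute exactly from the counts
they accompany. In the natural variant, flood-protected nests count as
flooded on their intervention day and trampling-protected nests are set
aside as censored (excluded from the denominators, a choice made explicit
here because published tables sometimes keep them in).
`protected_outcome_table()` breaks down protected-nest outcomes by cause
and protection duration.

`dsr_prediction_curve()` traces the posterior of $S$ along one covariate
with all other predictors at their scaled mean (0) and the year effect
fixed at 0 — averaging over years instead would mix annual level shifts
into a covariate effect, so the fixed-at-zero convention is used and
stated. Raw grid values map to the model scale through the stored
year-wise scaling averaged over years; points outside the observed range
warn but compute. `cumulative_hatch_probability()` multiplies 26 daily
survival probabilities into a laying-to-hatching success probability.
`autoplot()` methods draw the coefficient-interval plot (mean, 80% and
95% intervals, clear effects highlighted) and the prediction curves
(mean, dashed 95% bounds, shaded 80% band).

## Numerical choices and degenerate inputs

* Zero within-year variance in a covariate scales to 0 with a warning;
  fewer than 3 complete pairs, or a zero-variance column, yield `NA`
  correlations with a warning.
* A dataset with no failures leaves the intercept prior-dominated; the
  fitting functions warn, and the MLE oracle flags the boundary.
* Transition probabilities of exactly 0 or 1 against an observed outcome
  give a `-Inf` log-likelihood, handled as rejection during sampling.
* An intervention day outside a nest's active window is an error at
  encoding time; in simulation, designations voided by earlier failure
  are cleared.
* The activity cap retains a failure on exactly day 26 as a failure.

## Known limitations

* The generator's hazard layers are calibration choices; inferences about
  real meadows require the real monitoring data.
* The overall model is deliberately misspecified relative to the
  generator's full default scenario (floods, trampling and abandonment do
  not follow the logit surface), which is the realistic situation;
  coefficient recovery is therefore verified under the predation-only
  preset where truth is well-defined.
* Interval-censored likelihood variants (Mayfield-style) and female-level
  random effects are out of scope, as is any model comparison machinery.
* Reported posteriors for $\sigma_{\mathrm{year}}$ under the half-Cauchy
  prior can have 95% intervals reaching well below 1 when annual variation
  is modest; published tables in this literature sometimes show lower
  bounds pinned near 1, which would suggest a truncated prior or a
  reporting convention this package does not reproduce.
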