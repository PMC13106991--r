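# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All exported generators funnel their randomness through this so a
# scenario seed fixes every draw.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed scaling constants for the nest-age covariate: the day index runs over
# the 1..26 transition window, so its mean and sample SD are known a priori
# and do not depend on which nest-days were realized.
AGE_DAYS <- 1:26
age_scale <- function(t) (t - mean(AGE_DAYS)) / stats::sd(AGE_DAYS)

# Canonical fate labels and coefficient names, used consistently everywhere.
FATES_FAILED <- c("predated", "flooded", "trampled", "abandoned", "unknown_dead")
FATES_ALL <- c("hatched", FATES_FAILED, "unknown", "escaped")

COEF_NAMES <- c(
  "Intercept", "Nests", "Q.Nests", "Leks", "Q.Leks",
  "LayDate", "NestAge", "Incubation", "Path", "Edges", "Shore"
)

coef_names_for_variant <- function(variant) {
  if (identical(variant, "natural_only")) setdiff(COEF_NAMES, "Incubation") else COEF_NAMES
}

check_scenario <- function(scenario) {
  rlang::arg_match0(scenario, c("overall", "no_predation", "predation"))
}

check_variant <- function(variant) {
  rlang::arg_match0(variant, c("all_nests", "natural_only"))
}
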