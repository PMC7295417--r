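#' Canonical surgical strategies
#'
#' The nine surgical treatments compared by the model, with their treatment
#' setting. The retropubic mid-urethral sling (`retro-MUS`) is the reference
#' strategy against which relative cure effects are expressed. Anterior
#' repair, bladder-neck needle suspension, open and laparoscopic
#' colposuspension and the traditional sling are inpatient procedures; the
#' remainder are day-case procedures.
#'
#' @return A tibble with columns `id`, `setting` (`"day-case"` or
#'   `"inpatient"`) and `reference` (logical).
#' @export
#' @examples
#' sui_strategies()
sui_strategies <- function() {
  tibble::tibble(
    id = c(
      "retro-MUS", "transob-MUS", "single-incision", "injectable-agents",
      "trad-sling", "open-colpo", "lap-colpo", "bladder-neck-needle",
      "anterior-repair"
    ),
    setting = c(
      "day-case", "day-case", "day-case", "day-case",
      "inpatient", "inpatient", "inpatient", "inpatient", "inpatient"
    ),
    reference = c(TRUE, rep(FALSE, 8))
  )
}

# Odds ratios of cure vs retro-MUS from the published network meta-analysis.
# The injectable-agents row is a synthetic placeholder: the main-text table
# prints ORs for seven of the eight comparators only.
default_effects <- function() {
  tibble::tribble(
    ~strategy,             ~or_mean, ~or_median, ~crl_low, ~crl_high,
    "transob-MUS",            0.742,      0.738,    0.588,     0.923,
    "open-colpo",             0.874,      0.853,    0.544,     1.325,
    "lap-colpo",              0.605,      0.580,    0.315,     1.046,
    "trad-sling",             1.106,      1.061,    0.623,     1.846,
    "single-incision",        0.511,      0.504,    0.360,     0.699,
    "bladder-neck-needle",    0.368,      0.340,    0.154,     0.745,
    "anterior-repair",        0.235,      0.220,    0.105,     0.452,
    "injectable-agents",      0.330,      0.310,    0.140,     0.700
  )
}

# pooled absolute cure proportions after retro-MUS (meta-analysis medians);
# the 12- and 60-month rows anchor the Weibull recurrence fit
default_baseline_cure <- function() {
  tibble::tribble(
    ~time_months, ~cure_prop, ~crl_low, ~crl_high,
    6L,  0.776, 0.175, 0.983,
    12L, 0.841, 0.214, 0.990,
    24L, 0.784, 0.454, 0.941,
    36L, 0.341, 0.001, 0.995,
    60L, 0.329, 0.005, 0.979
  )
}

# Severe complications tracked by the model. Incidences, costs, utility
# decrements and durations are synthetic defaults (plausible placeholders, not
# published estimates); a (complication, strategy) pair absent from this table
# means the complication is assumed not to occur after that procedure.
# `ess` is the effective sample size of the beta uncertainty distribution.
default_complications <- function() {
  spread <- function(name, inc, cost, decr, dur, uui = FALSE) {
    tibble::tibble(
      name = name, strategy = names(inc), incidence = unname(inc),
      ess = 100, one_off_cost = cost, utility_decrement = decr,
      duration_cycles = as.integer(dur), triggers_uui = uui
    )
  }
  all9 <- sui_strategies()$id
  mus3 <- c("retro-MUS", "transob-MUS", "single-incision")
  dplyr::bind_rows(
    spread("infection", setNames(rep(0.03, 9), all9), 300, 0.05, 1L),
    spread("uui-onset",
           setNames(c(0.05, 0.05, 0.04, 0.03, 0.06, 0.06, 0.06, 0.05, 0.04), all9),
           150, 0, 0L, uui = TRUE),
    spread("voiding-difficulty",
           setNames(c(0.05, 0.03, 0.03, 0.01, 0.07, 0.04, 0.04, 0.05, 0.02), all9),
           450, 0.08, 3L),
    spread("perforation",
           setNames(c(0.030, 0.012, 0.010, 0.020),
                    c("retro-MUS", "transob-MUS", "single-incision", "trad-sling")),
           800, 0.10, 1L),
    spread("mesh-removal", setNames(c(0.020, 0.025, 0.020), mus3), 2500, 0.15, 2L),
    spread("short-term-pain",
           setNames(c(0.08, 0.08, 0.08, 0.04, 0.08, 0.08, 0.08, 0.08, 0.08), all9),
           100, 0.10, 2L),
    spread("persistent-pain",
           setNames(c(0.040, 0.045, 0.030, 0.010, 0.030, 0.020, 0.020, 0.020, 0.020), all9),
           600, 0.15, 12L)
  )
}

default_costs <- function() {
  list(
    procedure = tibble::tibble(
      strategy = sui_strategies()$id,
      cost = c(1400, 1350, 1100, 1500, 2900, 3200, 3400, 2400, 2600)
    ),
    followup_per_surgery = 350,
    containment_per_cycle = 25,
    cost_cv = 0.2
  )
}

default_utilities <- function() {
  tibble::tribble(
    ~name,                 ~value, ~ess,
    "u_pre_treatment_sui",   0.73,  200,
    "u_cured",               0.85,  200,
    "u_containment",         0.73,  200,
    "u_uui",                 0.65,  200
  )
}

default_uui_pathway <- function() {
  tibble::tribble(
    ~line, ~success_prob, ~duration_cycles, ~cost,
    1L, 0.35, 3L, 150,
    2L, 0.45, 6L, 250,
    3L, 0.55, 6L, 800
  )
}

#' Synthetic female life table
#'
#' Builds a smooth Gompertz-form all-cause mortality schedule as a stand-in
#' for a national female life table: the annual death probability rises
#' exponentially with age from about 0.001 at age 40, and is forced to 1 at
#' `max_age`. The values are synthetic placeholders with a realistic shape
#' (implied life expectancy at age 50 of roughly 35 further years), not
#' official statistics.
#'
#' @param max_age Oldest age in the table (final row has `qx = 1`).
#' @return A tibble with columns `age` (integer years, contiguous from 40)
#'   and `qx` (annual probability of death).
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' tail(lt)
synthetic_life_table <- function(max_age = 100) {
  stopifnot(max_age > 55)
  age <- 40:max_age
  qx <- pmin(1, 0.0009 * exp(0.09 * (age - 40)))
  qx[length(qx)] <- 1
  tibble::tibble(age = as.integer(age), qx = qx)
}

#' Default model parameter set
#'
#' Assembles the complete parameter set driving the base-case analysis.
#' Published quantities (cure odds ratios with 95% credible intervals,
#' reference-strategy cure proportions, re-treatment policy constants, the
#' 3.5% annual discount rate, the population scale of 15,000 surgeries per
#' year) carry provenance `"paper"`. Every quantity the main analysis text
#' does not print — complication incidences, unit costs, utility values and
#' decrements, the urge-incontinence treatment ladder, the life table — is a
#' documented synthetic placeholder with provenance `"synthetic-default"`,
#' and can be overridden through the configuration file.
#'
#' @return A validated `sui_parameters` object (see [validate_parameters()]),
#'   with a `provenance` attribute mapping each top-level field to
#'   `"paper"` or `"synthetic-default"`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$retreatment$p_seek_first_retreat
default_parameters <- function() {
  p <- structure(
    list(
      strategies = sui_strategies(),
      effects = default_effects(),
      baseline_cure = default_baseline_cure(),
      complications = default_complications(),
      retreatment = list(
        p_seek_first_retreat = 0.75,
        p_seek_second_retreat = 0.30,
        retreat_mix_retro = 0.55,
        retreat_mix_transob = 0.45,
        retreat_effect_multiplier = 0.90,
        max_surgeries = 3L
      ),
      economics = list(
        discount_rate_annual = 0.035,
        horizons = c("1y", "10y", "lifetime"),
        wtp_grid = seq(0, 50000, by = 1000),
        price_year = "2018/19"
      ),
      utilities = default_utilities(),
      costs = default_costs(),
      uui_pathway = default_uui_pathway(),
      life_table = synthetic_life_table(100),
      population = list(
        start_age = 50L,
        annual_affected = 15000,
        p_uui_baseline = 0.25
      )
    ),
    class = "sui_parameters"
  )
  attr(p, "provenance") <- tibble::tribble(
    ~field, ~provenance,
    "strategies",    "paper",
    "effects",       "paper",
    "effects.injectable-agents", "synthetic-default",
    "baseline_cure", "paper",
    "complications", "synthetic-default",
    "retreatment",   "paper",
    "economics",     "paper",
    "utilities",     "synthetic-default",
    "costs",         "synthetic-default",
    "uui_pathway",   "synthetic-default",
    "life_table",    "synthetic-default",
    "population",    "paper"
  )
  p
}

#' Randomised parameter sets for property testing
#'
#' Draws an internally consistent parameter set in which every family the
#' default set fills with synthetic placeholders (complication incidences,
#' one-off complication costs, utility decrements, complication durations,
#' procedure costs, urge-incontinence line success probabilities, health
#' utilities) is resampled uniformly within a configurable range. Published
#' quantities (effects, baseline cure, policy constants, discounting) are
#' left at their defaults. Day-case procedure cost ranges sit below
#' inpatient ranges, preserving the qualitative cost ordering. Every emitted
#' set passes [validate_parameters()].
#'
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param ranges Named list of `c(lo, hi)` ranges overriding the defaults:
#'   `complication_incidence` (0–0.2), `complication_cost` (100–3000),
#'   `utility_decrement` (0–0.3), `duration_cycles` (1–12),
#'   `daycase_cost` (800–1800), `inpatient_cost` (2000–3800),
#'   `uui_success` (0.2–0.6). A collapsed range `c(x, x)` pins the whole
#'   family to `x`.
#' @return A `sui_parameters` object.
#' @export
random_parameters <- function(seed, ranges = list()) {
  r <- modifyList(list(
    complication_incidence = c(0, 0.2),
    complication_cost = c(100, 3000),
    utility_decrement = c(0, 0.3),
    duration_cycles = c(1, 12),
    daycase_cost = c(800, 1800),
    inpatient_cost = c(2000, 3800),
    uui_success = c(0.2, 0.6)
  ), ranges)
  for (nm in names(r)) {
    if (r[[nm]][1] > r[[nm]][2]) {
      stop("inverted range for '", nm, "'", call. = FALSE)
    }
  }
  runif2 <- function(n, rng) runif(n, rng[1], rng[2])

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  p <- default_parameters()
  comp <- p$complications
  comp$incidence <- runif2(nrow(comp), r$complication_incidence)
  comp$one_off_cost <- runif2(nrow(comp), r$complication_cost)
  keep_zero <- comp$triggers_uui # uui-onset keeps decrement 0 (state utility applies)
  comp$utility_decrement <- ifelse(
    keep_zero, 0, runif2(nrow(comp), r$utility_decrement)
  )
  comp$duration_cycles <- ifelse(
    keep_zero, 0L,
    as.integer(round(runif2(nrow(comp), r$duration_cycles)))
  )
  p$complications <- comp

  day <- p$strategies$setting == "day-case"
  pc <- p$costs$procedure
  pc$cost[day] <- runif2(sum(day), r$daycase_cost)
  pc$cost[!day] <- runif2(sum(!day), r$inpatient_cost)
  p$costs$procedure <- pc

  uui <- p$uui_pathway
  uui$success_prob <- runif2(nrow(uui), r$uui_success)
  p$uui_pathway <- uui

  u_cured <- runif(1, 0.75, 0.95)
  u_pre <- runif(1, 0.55, u_cured)
  u_uui <- runif(1, 0.45, u_pre)
  p$utilities$value <- c(u_pre, u_cured, u_pre, u_uui)
  # decrements may not exceed the pre-treatment baseline utility
  p$complications$utility_decrement <-
    pmin(p$complications$utility_decrement, u_pre)

  prov <- attr(p, "provenance")
  prov$provenance[prov$field %in%
    c("complications", "costs", "uui_pathway", "utilities")] <- "synthetic-random"
  attr(p, "provenance") <- prov
  p
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}
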