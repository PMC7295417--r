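---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suicea)
```

## What the model is

`suicea` implements a patient-level (microsimulation) Markov model comparing
nine surgical treatments for stress urinary incontinence (SUI) and
stress-predominant mixed urinary incontinence in women, from a UK health
service and personal social services perspective. The retropubic
mid-urethral sling (retro-MUS) is the reference strategy; the eight
comparators are the transobturator sling, single-incision sling,
periurethral injectable agents, traditional suburethral sling, open and
laparoscopic colposuspension, bladder-neck needle suspension and anterior
vaginal repair. Each simulated woman enters the model at age 50 (the
midpoint of the 45–55 target population; a range, not a distribution, is
reported for the population, so a fixed midpoint is used and is
configurable), receives her assigned surgery, and is followed in monthly
cycles until one year, ten years, or death/age 100. Costs (GBP, 2018/19
prices) and quality-adjusted life-years are accumulated with 3.5% annual
discounting.

## Effectiveness model

Relative effectiveness enters as odds ratios (OR) of cure versus the
reference strategy, with 95% credible intervals, as estimated by a network
meta-analysis that this package consumes rather than re-estimates. Absolute
cure probabilities are obtained on the odds scale,

$$p' = \frac{\tfrac{p}{1-p}\,\mathrm{OR}}{1 + \tfrac{p}{1-p}\,\mathrm{OR}},$$

anchored at the reference strategy's pooled 12-month cure proportion
(0.841). The 12-month point is used as the single cure-assessment point
because it has by far the largest evidence base among the reported
follow-up times; the 6-month estimate is not separately modelled.

Long-term recurrence is extrapolated with a Weibull survival function
fitted through the 12-month (0.841) and 60-month (0.329) cure proportions.
With two anchors the fit is closed-form,

$$k = \frac{\ln(\ln s_2/\ln s_1)}{\ln(t_2/t_1)}, \qquad
  \lambda = \frac{t_1}{(-\ln s_1)^{1/k}},$$

giving shape `r round(tidy(fit_weibull_two_points(1, 0.841, 5, 0.329))$estimate[1], 4)`
and scale `r round(tidy(fit_weibull_two_points(1, 0.841, 5, 0.329))$estimate[2], 3)`
years; the intermediate 24- and 36-month rows are deliberately not used, and
no alternative parametric families are fitted. Because the shape exceeds 1
the recurrence hazard increases with time since surgery. The source
evidence does not state whether this curve describes recurrence after an
initial cure or time-to-failure from surgery; the package adopts the
conditional-recurrence reading. Concretely, whether a woman is cured is
decided at surgery with the 12-month probability; a cured woman faces no
recurrence draw during her first 12 post-operative months and the
conditional monthly hazard $1 - S(t+\delta)/S(t)$ applies thereafter. Under
this convention the expected cured fraction at 1 and 5 years reproduces
both anchors exactly, with no double counting of first-year failures.

Re-treatment policy: 75% of women whose first surgery fails (or whose cure
recurs) seek re-treatment, 30% after a second failure, and nobody after the
third — a maximum of three surgeries in all. Re-treatment is always a
mid-urethral sling, retropubic with probability 0.55 and transobturator
with 0.45, and is 90% as effective as the same procedure given as primary
surgery. The multiplier is applied on the probability scale (the source is
silent between probability and odds scales; the probability reading is the
simpler and was adopted) and the same 0.90 applies to the second and third
surgery. Women who do not seek re-treatment, or fail all three surgeries,
manage their symptoms with containment products permanently.

Women with urge incontinence — present at baseline with probability 0.25
(synthetic default, reflecting that a substantial share of surgical
candidates have stress-predominant mixed incontinence), or acquired as a
surgical complication — pass through three treatment lines (bladder
training, medication, botulinum toxin A), each with a synthetic success
probability, duration and cost; after a third failed line the condition
persists untreated.

## Cycle mechanics and numerical conventions

* **Cycle length is one month.** The source model does not state its cycle
  length; monthly resolution is needed for meaningful 1-year-horizon
  results and for complications lasting a few months. Annual life-table
  probabilities are converted under a constant within-year hazard,
  $q_m = 1-(1-q_a)^{1/12}$.
* **Event order within a cycle** is fixed: mortality, surgery (cure
  determination and complication onset), recurrence, re-treatment seeking,
  urge-incontinence line progression, complication-duration bookkeeping,
  accrual. The source is silent on within-cycle ordering.
* **Half-cycle discounting.** Accruals are discounted at the cycle
  midpoint, $(1+r)^{-(t-\frac12)/12}$; one-off costs (procedures,
  complication management) use the same factor as the cycle in which they
  occur. A woman who dies in a cycle accrues nothing in that cycle.
* **Utilities.** The cycle utility is the base-state utility (cured,
  pre-treatment SUI, containment, or urge incontinence — the urge state
  dominates when present) minus the decrements of active complications,
  floored at zero. "Incontinent awaiting re-treatment" and "containment"
  share the pre-treatment utility value by default, as the source does not
  distinguish them; utilities are not age-adjusted over the lifetime
  horizon (the source does not state an adjustment; an optional schedule
  was considered and left out of the base case).
* **Re-treatment timing.** A woman who seeks re-treatment is operated in
  the next cycle; non-seekers move to containment permanently. The source
  is silent on timing.
* **Seeking probabilities** (75%/30%) are interpreted per failure event,
  not per cycle at risk.
* **No surgery-attributable mortality**: only all-cause life-table
  mortality operates.
* **Persistent pain** lasts 1 year in the base case (the source varies 3
  and 5 years only in sensitivity analysis and never states a base-case
  value; 1 year is the package's flagged default).
* **Common random numbers.** Each woman's draws come from a substream
  keyed by her index, shared across strategies and, in the probabilistic
  analysis, across parameter draws. This reduces the Monte Carlo variance
  of incremental comparisons and makes results independent of execution
  order; it affects precision only, not expectations.

## Parameters: published values and synthetic placeholders

Everything printed in the source's main text ships as the default: the
odds-ratio table with credible intervals, the reference cure proportions,
the policy constants (75%, 30%, 55/45, 0.90, three surgeries), the 3.5%
discount rate, the 2018/19 price year, and the population scale of 15,000
surgeries per year. One gap is worth flagging: the published odds-ratio
table covers seven of the eight comparators, so the injectable-agents OR is
itself a synthetic placeholder (median 0.310, CrI 0.140–0.700), chosen so
that its effectiveness ranks between the needle suspension and the
transobturator sling.

Every remaining input — complication incidences, complication costs,
utility values and decrements, procedure and follow-up costs, the
urge-incontinence ladder, the life table — appears only in supplementary
material that this package does not reproduce. These ship as documented
synthetic defaults flagged `provenance = "synthetic-default"`: magnitudes
were chosen once to keep the qualitative structure plausible (day-case
procedures cheaper than inpatient ones; persistent pain rarer than
short-term pain; mesh removal only after mesh procedures; a Gompertz-shaped
female life table with life expectancy of roughly 35 further years at age
50) and are deliberately *not* calibrated to reproduce the published cost
and QALY tables — recovering unpublished inputs from published outputs is
ill-posed. Consequently the package's base-case costs, QALYs, acceptability
curves and value-of-information magnitudes are structurally faithful but
numerically its own; the exactly reproducible quantities are the Weibull
fit, the odds-ratio conversions, the policy arithmetic and the population
scaling of the value of information. Users with access to the real inputs
can override any field through the YAML configuration.

`random_parameters()` resamples all synthetic families uniformly within
documented ranges for property testing (complication incidence 0–0.2,
complication cost £100–£3,000, decrement 0–0.3, day-case cost below
inpatient cost, urge-line success 0.2–0.6). A collapsed range pins a whole
family to a point; because the shipped defaults vary across strategies and
complications, collapsing ranges yields a homogeneous set rather than the
default set itself.

## Probabilistic sensitivity analysis and value of information

Each draw samples: odds ratios from lognormal distributions with
`meanlog = log(median)` (so the printed median is reproduced exactly) and
`sdlog` from the credible-interval width; probabilities and utilities from
beta distributions parameterised by mean and effective sample size
(default 100–200); and costs from gamma distributions with a common 20%
coefficient of variation. The reference cure proportions and the Weibull
parameters are held fixed: their printed intervals describe between-study
predictive spread rather than uncertainty in the pooled median, and
propagating them as sampling distributions would dominate every other
source of uncertainty. The count phrase "1000 simulations" in the source is
ambiguous between parameter draws and inner patients; both counts are
exposed (`n_draws`, `n_patients_per_draw`) with defaults of 1000 each.

Acceptability curves report, per willingness-to-pay value, the fraction of
draws in which each strategy has the maximal net monetary benefit
(`wtp * QALY − cost`); exact ties split their draw equally so columns sum
to one (ties are measure-zero for continuous draws but arise in degenerate
test configurations). Per-person EVPI is the mean maximal net benefit minus
the maximal mean net benefit. Population EVPI multiplies by 15,000 persons
per year and the number of years, undiscounted by default because the
published population figures are exact multiples of the per-year value; a
discounted variant is available behind the `discount_rate` argument.

EVPPI uses a single-loop regression estimator — each strategy's net benefit
is smoothed on the parameter group with additive penalised splines
(`mgcv::gam`), and the value computed from the fitted conditional means —
rather than nested Monte Carlo, which would be prohibitively slow at desk
scale. The estimate is clamped to its analytic bounds `[0, EVPI]`. On very
small samples (fewer than about 30 draws or 10 draws per covariate) the
smoother degrades to a linear conditional-mean model. The estimator is
validated in the test suite against a closed-form two-strategy crossing
problem at 10,000 draws (5% tolerance) and against the full-information and
irrelevant-parameter limits.

## Deterministic scenarios

`apply_scenario()` supports the published sensitivity analyses as pure,
idempotent overrides: mesh-removal incidence after the two sling procedures
raised to 10% or 20%; persistent-pain duration of 3 or 5 years;
persistent-pain incidence after the slings of 10% or 20%; and alternative
short- and long-term reference cure proportions feeding the Weibull fit.

## Problem sizes and degenerate inputs

Defaults are desk-scale — 2,000 patients per strategy for the deterministic
base case and 200 parameter draws for the probabilistic analysis — with
flags to reach the published 1,000-draw scale. The test suite validates the
engine against closed forms on a degenerate two-state reduction (certain
cure, flat mortality) at 20,000 patients, checks pathway rules over 10,000
fuzzed patients, and verifies parameter recovery at 100,000 draws.
Degenerate inputs are defined behaviour throughout: boundary cure
proportions bypass the odds transform (the odds are degenerate there),
collapsed credible intervals and infinite effective sample sizes sample to
the mean exactly, a zero discount rate gives unit discount factors, and a
numerically extinct cured fraction yields a recurrence probability of one.

## Known limitations

* Synthetic placeholder inputs mean absolute costs and QALYs are not
  comparable to the published tables; only structure, policy arithmetic and
  relative mechanics are.
* The Weibull time-shape estimated for the reference strategy is shared by
  all comparators after transforming the cure level through the odds ratio;
  comparator-specific recurrence shapes are not identifiable from the
  consumed evidence.
* A single cure-assessment point (12 months) compresses differences in
  early response between procedures.
* The engine is a fixed-order monthly-cycle model, not a continuous-time
  discrete-event simulation; within-cycle competing risks are resolved by
  the documented event order.
* Costs are health-system only; out-of-pocket containment costs are not
  modelled.
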