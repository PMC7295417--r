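# suicea

Cost-utility microsimulation of nine surgical treatments for stress
urinary incontinence (SUI) and stress-predominant mixed urinary
incontinence in women.

Surgery is the recommended treatment when conservative management of SUI
fails, but the available operations — from modern day-case mid-urethral
slings to older inpatient procedures such as colposuspension — differ in
cost, cure rate and complication profile, and there is no surgical
consensus on which to use. `suicea` is aimed at health-economic modellers
who need a transparent, scriptable implementation of a patient-level
Markov (microsimulation) cost-utility model of this decision: it simulates
individual women in monthly cycles through surgery, recurrence,
re-treatment, complications, an urge-incontinence treatment ladder and
containment, and propagates parameter uncertainty through probabilistic
sensitivity and value-of-information analysis.

## The model in brief

* Nine strategies; the retropubic mid-urethral sling (retro-MUS) is the
  reference. Relative effectiveness enters as network-meta-analysis odds
  ratios of cure, converted to absolute probabilities on the odds scale:
  *p′ = odds·OR / (1 + odds·OR)*, anchored at the reference's pooled
  12-month cure proportion (0.841).
* Recurrence after cure follows a Weibull survival function *S(t) =
  exp(−(t/λ)^k)* fitted in closed form through the 12-month (0.841) and
  60-month (0.329) cure proportions, discretised to conditional monthly
  probabilities *1 − S(t+δ)/S(t)*.
* At most three surgeries; 75% seek re-treatment after a first failure,
  30% after a second; re-treatment is retro-MUS (55%) or the
  transobturator sling (45%) at 90% of primary effectiveness; after the
  third failure, containment products permanently.
* Costs (GBP 2018/19) and QALYs accrue with mid-cycle discounting at 3.5%
  per year over 1-year, 10-year or lifetime horizons.
* Probabilistic analysis samples odds ratios (lognormal), probabilities
  and utilities (beta) and costs (gamma); outputs include
  cost-effectiveness acceptability curves (probability of maximal net
  monetary benefit, NMB = WTP·QALY − cost), per-person and population
  EVPI, and regression-based EVPPI per parameter group.

Published main-text values (odds ratios, cure anchors, policy constants,
discounting, 15,000 treated women per year) ship as defaults; every
supplementary-only input (complication incidences, unit costs, utilities,
the life table, the urge-incontinence ladder) is a documented synthetic
placeholder flagged `synthetic-default`, overridable via a YAML
configuration. Absolute cost/QALY levels are therefore the package's own;
see `vignette("model-methods")` for exactly which quantities are
reproducible and why.

## Worked example

```r
library(suicea)
p <- load_parameters(system.file("extdata", "default_config.yaml",
                                 package = "suicea"))

# recurrence extrapolation from the two cure anchors
w <- fit_weibull_two_points(1, 0.841, 5, 0.329)
w
#> <sui_weibull> shape = 1.1553, scale = 4.5621 years

# absolute 12-month cure after the transobturator sling (OR 0.738)
or_to_prob(0.841, 0.738)
#> [1] 0.7960644

# simulate all nine strategies over 10 years and rank them
res <- dplyr::bind_rows(lapply(p$strategies$id, function(s)
  simulate_cohort(p, s, n = 300, horizon = "10y", seed = 42)))
compute_icers(res)
#> Incremental cost-effectiveness (ordered by mean cost)
#> # A tibble: 9 × 7
#>   strategy             cost  qaly inc_cost inc_qaly    icer status
#>   <chr>               <dbl> <dbl>    <dbl>    <dbl>   <dbl> <chr>
#> 1 single-incision     4229.  6.56      NA   NA          NA  reference
#> 2 retro-MUS           4380.  6.58     151.   0.0230   6565. frontier
#> 3 transob-MUS         4451.  6.56      NA   NA          NA  dominated
#> 4 injectable-agents   4734.  6.53      NA   NA          NA  dominated
#> 5 bladder-neck-needle 5608.  6.53      NA   NA          NA  dominated
#> 6 trad-sling          5722.  6.53      NA   NA          NA  dominated
#> 7 anterior-repair     5944.  6.48      NA   NA          NA  dominated
#> 8 open-colpo          6101.  6.59    1721.   0.0121 141858. frontier
#> 9 lap-colpo           6380.  6.58      NA   NA          NA  dominated

# population value of a per-person EVPI of £11,857 over 10 years
population_evpi(11857, 15000, 10)
#> [1] 1778550000
```

The fitted Weibull shape above 1 means the recurrence hazard rises with
time since surgery. In the ICER table, a `dominated` strategy is more
costly and no more effective than an alternative; the `icer` column gives
the incremental cost per QALY between successive members of the efficient
frontier (here, at a £20,000/QALY threshold, retro-MUS would be the
cost-effective choice at this horizon under the synthetic default inputs).
The final line scales a per-person expected value of perfect information
to the UK population assuming 15,000 women treated per year.

The probabilistic pipeline, acceptability-curve and value-of-information
outputs are produced by `run_psa()`, `ceac()`, `evpi_per_person()`,
`evppi()` and `run_psa_analysis()`; `autoplot()` draws the
cost-effectiveness plane and CEACs. A thin command-line wrapper is
installed at `inst/cli/suicea.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "suicea.R", package = "suicea"))')" \
  basecase --horizon 10y --n-patients 2000 --seed 1 --out results/
```

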