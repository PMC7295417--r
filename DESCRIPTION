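Package: suicea
Title: Cost-Utility Microsimulation of Surgical Treatments for Stress
    Urinary Incontinence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Markov microsimulation comparing nine surgical
    treatments for stress urinary incontinence and stress-predominant mixed
    urinary incontinence from a UK health-service perspective. Converts
    network-meta-analysis odds ratios into absolute cure probabilities,
    extrapolates recurrence with a two-point Weibull fit, simulates
    treatment and re-treatment pathways with complications and an urge
    incontinence treatment ladder, and accumulates discounted costs and
    quality-adjusted life-years. Includes deterministic scenario analyses,
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and expected value of (partial) perfect
    information analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
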