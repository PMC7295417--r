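#' Convert a baseline probability through an odds ratio
#'
#' Applies an odds ratio on the odds scale:
#' \eqn{p' = \frac{\mathrm{odds} \cdot \mathrm{OR}}{1 + \mathrm{odds}
#' \cdot \mathrm{OR}}} with \eqn{\mathrm{odds} = p/(1-p)}. Used to turn the
#' reference strategy's absolute cure probability into each comparator's.
#'
#' @param baseline_p Baseline probability, strictly inside `(0, 1)`
#'   (vectorised).
#' @param or Odds ratio, positive (vectorised).
#' @return Transformed probabilities in `(0, 1)`, increasing in `or`.
#' @export
#' @examples
#' or_to_prob(0.841, 0.738) # transobturator sling 12-month cure
or_to_prob <- function(baseline_p, or) {
  if (any(baseline_p <= 0 | baseline_p >= 1)) {
    stop("baseline_p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(or <= 0)) stop("or must be positive", call. = FALSE)
  odds <- baseline_p / (1 - baseline_p) * or
  odds / (1 + odds)
}

#' Fit a lognormal distribution to a median and 95% credible interval
#'
#' Chooses `meanlog = log(median)` so sampling reproduces the printed
#' median exactly, and `sdlog` from the width of the interval on the log
#' scale, `(log(high) - log(low)) / (2 * 1.959964)`. This is the sampling
#' distribution used for the cure odds ratios in the probabilistic
#' sensitivity analysis.
#'
#' @param median,low,high Positive reals with `low <= median <= high`.
#' @return A list with elements `mu` (meanlog) and `sigma` (sdlog).
#' @export
#' @examples
#' fit_lognormal_from_crl(0.738, 0.588, 0.923)
fit_lognormal_from_crl <- function(median, low, high) {
  if (any(c(median, low, high) <= 0)) {
    stop("median and bounds must be positive", call. = FALSE)
  }
  if (low > median || median > high) {
    stop("bounds must bracket the median: low <= median <= high", call. = FALSE)
  }
  list(
    mu = log(median),
    sigma = (log(high) - log(low)) / (2 * qnorm(0.975))
  )
}

#' Sample cure odds ratios for one probabilistic draw
#'
#' Draws one odds ratio per comparator strategy from the lognormal
#' distribution fitted to its median and 95% credible interval
#' ([fit_lognormal_from_crl()]); the reference strategy's odds ratio is
#' fixed at 1. A degenerate interval (`low == median == high`) yields the
#' median exactly.
#'
#' @param p A `sui_parameters` object (only `p$effects` is used).
#' @param n Number of draws.
#' @return A tibble with columns `draw`, `strategy` and `or` covering all
#'   nine strategies per draw.
#' @export
sample_effects <- function(p, n = 1) {
  e <- p$effects
  fits <- purrr::pmap(
    list(e$or_median, e$crl_low, e$crl_high),
    fit_lognormal_from_crl
  )
  draws <- purrr::map2(fits, seq_len(nrow(e)), function(f, i) {
    if (f$sigma == 0) rep(exp(f$mu), n) else exp(rnorm(n, f$mu, f$sigma))
  })
  ref <- p$strategies$id[p$strategies$reference][1]
  tibble::tibble(
    draw = rep(seq_len(n), nrow(e) + 1),
    strategy = rep(c(ref, e$strategy), each = n),
    or = c(rep(1, n), unlist(draws))
  )
}

#' Absolute cure probability for a given surgery
#'
#' Combines the reference strategy's 12-month cure probability with the
#' strategy's cure odds ratio ([or_to_prob()]); for second and third
#' surgeries the result is multiplied by the re-treatment effectiveness
#' multiplier (0.90 by default) and clamped to `[0, 1]`. Re-treatment is
#' restricted to the two mid-urethral sling procedures, so requesting any
#' other strategy with `surgery_number > 1` is an error. Boundary baseline
#' probabilities (0 or 1) are passed through unchanged — the odds are then
#' degenerate and no finite odds ratio moves them — which supports
#' degenerate always-cured configurations.
#'
#' @param p A `sui_parameters` object.
#' @param strategy Strategy id.
#' @param surgery_number 1, 2 or 3.
#' @param or Odds ratio of cure versus the reference for `strategy`;
#'   defaults to the median estimate in `p` (1 for the reference).
#' @return A cure probability in `[0, 1]`.
#' @export
#' @examples
#' p <- default_parameters()
#' effective_cure_prob(p, "retro-MUS", 1)
#' effective_cure_prob(p, "transob-MUS", 2)
effective_cure_prob <- function(p, strategy, surgery_number, or = NULL) {
  stopifnot(inherits(p, "sui_parameters"))
  if (!strategy %in% p$strategies$id) {
    stop("unknown strategy: ", strategy, call. = FALSE)
  }
  if (!surgery_number %in% 1:3) {
    stop("surgery_number must be 1, 2 or 3", call. = FALSE)
  }
  if (surgery_number > 1 && !strategy %in% c("retro-MUS", "transob-MUS")) {
    stop(
      "re-treatment is restricted to retro-MUS and transob-MUS; got ",
      strategy,
      call. = FALSE
    )
  }
  if (is.null(or)) {
    ref <- p$strategies$id[p$strategies$reference][1]
    or <- if (strategy == ref) 1 else {
      p$effects$or_median[p$effects$strategy == strategy]
    }
  }
  base <- p$baseline_cure$cure_prop[p$baseline_cure$time_months == 12L]
  # boundary baselines are invariant under any finite odds ratio
  prob <- if (base <= 0 || base >= 1) base else or_to_prob(base, or)
  if (surgery_number > 1) {
    prob <- prob * p$retreatment$retreat_effect_multiplier
  }
  min(max(prob, 0), 1)
}
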