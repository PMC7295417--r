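#' Fit a Weibull recurrence-time distribution through two cure proportions
#'
#' Solves for the Weibull shape `k` and scale `lambda` whose survival
#' function \eqn{S(t) = \exp(-(t/\lambda)^k)} passes exactly through two
#' observed cure proportions, typically the 1-year and 5-year proportions
#' still cured after the reference surgery. The solution is closed form:
#' \deqn{k = \frac{\ln(\ln s_2 / \ln s_1)}{\ln(t_2 / t_1)}, \qquad
#'       \lambda = \frac{t_1}{(-\ln s_1)^{1/k}}.}
#'
#' @param t1,t2 Times in years, `0 < t1 < t2`.
#' @param s1,s2 Proportions still cured at `t1` and `t2`; survival must
#'   decrease (`0 < s2 < s1 < 1`).
#' @return An object of class `sui_weibull` with elements `shape` and
#'   `scale` (years).
#' @export
#' @examples
#' w <- fit_weibull_two_points(1, 0.841, 5, 0.329)
#' weibull_survival(w, c(1, 2, 5))
fit_weibull_two_points <- function(t1, s1, t2, s2) {
  if (!(t1 > 0 && t2 > t1)) {
    stop("times must satisfy 0 < t1 < t2", call. = FALSE)
  }
  if (any(c(s1, s2) <= 0) || any(c(s1, s2) >= 1)) {
    stop("cure proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (s2 >= s1) {
    stop("survival must decrease: s2 < s1 is required", call. = FALSE)
  }
  shape <- log(log(s2) / log(s1)) / log(t2 / t1)
  scale <- t1 / (-log(s1))^(1 / shape)
  structure(list(shape = shape, scale = scale), class = "sui_weibull")
}

#' Weibull survival function
#'
#' Proportion still cured at `t` years after the initial cure:
#' \eqn{S(t) = \exp(-(t/\lambda)^k)}.
#'
#' @param w A `sui_weibull` object.
#' @param t Time in years (vectorised, non-negative).
#' @return Survival probabilities in `[0, 1]`.
#' @export
weibull_survival <- function(w, t) {
  stopifnot(inherits(w, "sui_weibull"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-(t / w$scale)^w$shape)
}

#' Conditional per-cycle recurrence probability
#'
#' Probability that a woman still cured at `t` years recurs within the next
#' `dt` years: \eqn{1 - S(t+dt)/S(t)}. This is the discrete-cycle hazard
#' used by the microsimulation; chaining two half-cycles reproduces one
#' full cycle exactly.
#'
#' @param w A `sui_weibull` object.
#' @param t Time in years since cure (vectorised, non-negative).
#' @param dt Cycle length in years (positive).
#' @return Recurrence probabilities in `[0, 1]`; returns 1 where `S(t)`
#'   underflows to zero.
#' @export
cycle_recurrence_prob <- function(w, t, dt) {
  stopifnot(inherits(w, "sui_weibull"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  st <- weibull_survival(w, t)
  p <- ifelse(st == 0, 1, 1 - weibull_survival(w, t + dt) / st)
  pmin(pmax(p, 0), 1)
}

#' @export
print.sui_weibull <- function(x, ...) {
  cat(sprintf("<sui_weibull> shape = %.4f, scale = %.4f years\n",
              x$shape, x$scale))
  invisible(x)
}

#' @rdname fit_weibull_two_points
#' @param x A `sui_weibull` object.
#' @param ... Unused.
#' @method tidy sui_weibull
#' @export
tidy.sui_weibull <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale)
  )
}

#' @rdname fit_weibull_two_points
#' @method glance sui_weibull
#' @export
glance.sui_weibull <- function(x, ...) {
  tibble::tibble(
    shape = x$shape,
    scale = x$scale,
    median_recurrence_years = x$scale * log(2)^(1 / x$shape),
    increasing_hazard = x$shape > 1
  )
}
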