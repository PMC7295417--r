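#' Discount factor
#'
#' Present-value factor \eqn{(1+r)^{-t}} for an amount accruing `t` years
#' from now at annual rate `r`.
#'
#' @param rate_annual Annual discount rate (non-negative); 0.035 in the
#'   base case.
#' @param t_years Time in years (vectorised, non-negative).
#' @return Discount factors in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(0.035, 2) * 100
discount_factor <- function(rate_annual, t_years) {
  if (rate_annual < 0) stop("rate_annual must be non-negative", call. = FALSE)
  if (any(t_years < 0)) stop("t_years must be non-negative", call. = FALSE)
  (1 + rate_annual)^(-t_years)
}

#' Incremental cost-effectiveness table with dominance classification
#'
#' Orders strategies by ascending mean cost, labels strictly dominated
#' strategies (at least as costly as, and no more effective than, some
#' other strategy, with one inequality strict), removes extendedly
#' dominated strategies (those whose ICER exceeds that of the next frontier
#' member, i.e. dominated by a mixture of two alternatives) by a repeated
#' frontier sweep, and computes ICERs between successive members of the
#' efficient frontier. ICERs along the frontier are strictly increasing by
#' construction.
#'
#' @param results A data frame with columns `strategy`, `mean_cost` and
#'   `mean_qaly` (one row per strategy; at least two), e.g. bound rows from
#'   [simulate_cohort()]. Columns named `cost`/`qaly` are also accepted.
#' @return A tibble ordered by cost with columns `strategy`, `cost`,
#'   `qaly`, `inc_cost`, `inc_qaly` (versus the previous frontier member,
#'   `NA` for the cheapest strategy), `icer` and `status` (`"reference"`,
#'   a finite ICER implied by `"frontier"`, `"dominated"` or
#'   `"extendedly-dominated"`).
#' @export
#' @examples
#' res <- tibble::tibble(
#'   strategy = c("A", "B", "C"),
#'   mean_cost = c(100, 180, 300),
#'   mean_qaly = c(1.0, 1.2, 1.1)
#' )
#' compute_icers(res)
compute_icers <- function(results) {
  df <- tibble::as_tibble(results)
  if (!"mean_cost" %in% names(df) && "cost" %in% names(df)) {
    df$mean_cost <- df$cost
  }
  if (!"mean_qaly" %in% names(df) && "qaly" %in% names(df)) {
    df$mean_qaly <- df$qaly
  }
  stopifnot(all(c("strategy", "mean_cost", "mean_qaly") %in% names(df)))
  if (nrow(df) < 2) {
    stop("at least two strategies are required", call. = FALSE)
  }
  df <- df[order(df$mean_cost, df$mean_qaly), ]
  n <- nrow(df)
  cost <- df$mean_cost
  qaly <- df$mean_qaly

  status <- rep("frontier", n)
  # strict dominance: another strategy is no more costly and no less
  # effective, with at least one strict inequality
  for (i in seq_len(n)) {
    dominated <- any(
      cost <= cost[i] & qaly >= qaly[i] &
        (cost < cost[i] | qaly > qaly[i])
    )
    if (dominated) status[i] <- "dominated"
  }
  # extended dominance: repeated sweep removing frontier members whose ICER
  # exceeds the next frontier ICER
  repeat {
    idx <- which(status == "frontier")
    if (length(idx) < 3) break
    ic <- diff(cost[idx]) / diff(qaly[idx])
    bad <- which(ic[-length(ic)] > ic[-1])
    if (length(bad) == 0) break
    status[idx[bad[1] + 1]] <- "extendedly-dominated"
  }

  idx <- which(status == "frontier")
  inc_cost <- rep(NA_real_, n)
  inc_qaly <- rep(NA_real_, n)
  icer <- rep(NA_real_, n)
  if (length(idx) > 1) {
    for (j in 2:length(idx)) {
      i <- idx[j]
      prev <- idx[j - 1]
      inc_cost[i] <- cost[i] - cost[prev]
      inc_qaly[i] <- qaly[i] - qaly[prev]
      icer[i] <- if (inc_qaly[i] == 0) Inf else inc_cost[i] / inc_qaly[i]
    }
  }
  status[idx[1]] <- "reference"

  out <- tibble::tibble(
    strategy = df$strategy,
    cost = cost,
    qaly = qaly,
    inc_cost = inc_cost,
    inc_qaly = inc_qaly,
    icer = icer,
    status = status
  )
  class(out) <- c("sui_icer", class(out))
  out
}

#' Write an ICER table as delimited text
#'
#' @param tab A tibble from [compute_icers()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_icer_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sui_icer <- function(x, ...) {
  cat("Incremental cost-effectiveness (ordered by mean cost)\n")
  NextMethod()
}
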