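#' Draw one realisation of the uncertain parameters
#'
#' Samples every parameter with an uncertainty specification: cure odds
#' ratios from the lognormal fitted to their median and 95% credible
#' interval, complication incidences and utility values (state utilities
#' and complication decrements) from beta distributions parameterised by
#' mean and effective sample size (`alpha = m * ess`, `beta = (1-m) * ess`),
#' and unit costs (procedure, follow-up, containment, complication
#' management, urge-incontinence lines) from gamma distributions with a
#' common coefficient of variation. Complication management costs and
#' decrements are drawn once per complication type and shared across
#' strategies. Degenerate specifications (`ess = Inf`, `cost_cv = 0`,
#' collapsed credible intervals, or boundary means) pass the mean through
#' exactly; all other parameters are fixed.
#'
#' @param p A `sui_parameters` object.
#' @return A `sui_parameters` realisation with attributes `psa_or` (named
#'   odds-ratio vector including the reference at 1) and `psa_record`
#'   (named numeric vector of every sampled value, with prefixes `or.`,
#'   `cinc.`, `util.`, `decr.` and `cost.` defining the default
#'   expected-value-of-partial-perfect-information parameter groups).
#' @export
sample_parameter_set <- function(p) {
  stopifnot(inherits(p, "sui_parameters"))
  record <- c()
  rec <- function(name, value) record[name] <<- value

  q <- p

  # odds ratios ~ lognormal(median, 95% CrI)
  e <- p$effects
  or <- setNames(rep(1, nrow(p$strategies)), p$strategies$id)
  for (i in seq_len(nrow(e))) {
    f <- fit_lognormal_from_crl(e$or_median[i], e$crl_low[i], e$crl_high[i])
    or[e$strategy[i]] <- if (f$sigma == 0) exp(f$mu) else exp(rnorm(1, f$mu, f$sigma))
    rec(paste0("or.", e$strategy[i]), or[[e$strategy[i]]])
  }

  rbeta_mean <- function(m, ess, what) {
    if (!is.finite(ess)) {
      if (is.na(ess) || ess <= 0) stop("non-positive beta effective sample size for ", what, call. = FALSE)
      return(m)
    }
    if (ess <= 0) stop("non-positive beta effective sample size for ", what, call. = FALSE)
    if (m <= 0 || m >= 1) return(m)
    rbeta(1, m * ess, (1 - m) * ess)
  }
  rgamma_mean <- function(m, cv, what) {
    if (cv < 0) stop("negative cost coefficient of variation for ", what, call. = FALSE)
    if (cv == 0 || m == 0) return(m)
    rgamma(1, shape = 1 / cv^2, scale = m * cv^2)
  }

  # complication incidences ~ beta, per (complication, strategy)
  cm <- q$complications
  for (i in seq_len(nrow(cm))) {
    v <- rbeta_mean(cm$incidence[i], cm$ess[i],
                    paste(cm$name[i], cm$strategy[i]))
    cm$incidence[i] <- v
    rec(paste0("cinc.", cm$name[i], ".", cm$strategy[i]), v)
  }
  # complication management cost and decrement, shared per complication type
  cv <- p$costs$cost_cv
  for (nm in unique(cm$name)) {
    i <- which(cm$name == nm)
    cost <- rgamma_mean(cm$one_off_cost[i[1]], cv, nm)
    cm$one_off_cost[i] <- cost
    rec(paste0("cost.comp.", nm), cost)
    if (cm$utility_decrement[i[1]] > 0) {
      decr <- rbeta_mean(cm$utility_decrement[i[1]], cm$ess[i[1]], nm)
      cm$utility_decrement[i] <- decr
      rec(paste0("decr.", nm), decr)
    }
  }
  q$complications <- cm

  # state utilities ~ beta
  u <- q$utilities
  for (i in seq_len(nrow(u))) {
    u$value[i] <- rbeta_mean(u$value[i], u$ess[i], u$name[i])
    rec(paste0("util.", u$name[i]), u$value[i])
  }
  q$utilities <- u

  # unit costs ~ gamma
  pc <- q$costs$procedure
  for (i in seq_len(nrow(pc))) {
    pc$cost[i] <- rgamma_mean(pc$cost[i], cv, pc$strategy[i])
    rec(paste0("cost.proc.", pc$strategy[i]), pc$cost[i])
  }
  q$costs$procedure <- pc
  q$costs$followup_per_surgery <-
    rgamma_mean(p$costs$followup_per_surgery, cv, "followup")
  rec("cost.followup", q$costs$followup_per_surgery)
  q$costs$containment_per_cycle <-
    rgamma_mean(p$costs$containment_per_cycle, cv, "containment")
  rec("cost.containment", q$costs$containment_per_cycle)
  uu <- q$uui_pathway
  for (i in seq_len(nrow(uu))) {
    uu$cost[i] <- rgamma_mean(uu$cost[i], cv, paste0("uui line ", uu$line[i]))
    rec(paste0("cost.uui.line", uu$line[i]), uu$cost[i])
  }
  q$uui_pathway <- uu

  attr(q, "psa_or") <- or
  attr(q, "psa_record") <- record
  q
}

default_parameter_groups <- function(record_names) {
  list(
    effects = grep("^or\\.", record_names, value = TRUE),
    complication_incidence = grep("^cinc\\.", record_names, value = TRUE),
    utilities = grep("^(util|decr)\\.", record_names, value = TRUE),
    costs = grep("^cost\\.", record_names, value = TRUE)
  )
}

#' Run a probabilistic sensitivity analysis
#'
#' For each of `n_draws` parameter draws ([sample_parameter_set()]), runs a
#' microsimulation cohort for every strategy with common random numbers
#' (the same patient substreams across strategies and draws) and records
#' the per-draw mean discounted cost and QALYs. Deterministic given `seed`.
#'
#' @param p A `sui_parameters` object.
#' @param n_draws Number of parameter draws (at least 2).
#' @param n_patients_per_draw Women simulated per draw and strategy.
#' @param horizon `"1y"`, `"10y"` or `"lifetime"`.
#' @param seed Integer seed.
#' @return A `sui_psa` tibble with columns `draw`, `strategy`, `cost`,
#'   `qaly`, carrying attributes `parameters` (one row per draw of every
#'   sampled value), `groups` (named parameter groups for [evppi()]),
#'   `seed`, `n_patients_per_draw` and `horizon`.
#' @export
run_psa <- function(p, n_draws = 1000, n_patients_per_draw = 1000,
                    horizon = "lifetime", seed = 1) {
  stopifnot(inherits(p, "sui_parameters"))
  if (n_draws < 2) stop("n_draws must be at least 2", call. = FALSE)
  rows <- vector("list", n_draws)
  recs <- vector("list", n_draws)
  strategies <- p$strategies$id
  # one inner seed shared by all draws and strategies: common random numbers
  # in both dimensions, so degenerate distributions reproduce the base case
  # exactly and incremental comparisons have reduced Monte Carlo variance
  cohort_seed <- substream_seed(seed, 500001L)
  for (d in seq_len(n_draws)) {
    set.seed(substream_seed(seed, d))
    ps <- sample_parameter_set(p)
    ctx <- compile_model(ps, horizon, or = attr(ps, "psa_or"))
    res <- lapply(strategies, function(s) {
      r <- simulate_cohort(ctx, s, n = n_patients_per_draw, seed = cohort_seed)
      tibble::tibble(draw = d, strategy = s,
                     cost = r$mean_cost, qaly = r$mean_qaly)
    })
    rows[[d]] <- dplyr::bind_rows(res)
    recs[[d]] <- attr(ps, "psa_record")
  }
  out <- dplyr::bind_rows(rows)
  params <- tibble::as_tibble(do.call(rbind, recs))
  params <- dplyr::bind_cols(tibble::tibble(draw = seq_len(n_draws)), params)
  attr(out, "parameters") <- params
  attr(out, "groups") <- default_parameter_groups(names(params))
  attr(out, "seed") <- seed
  attr(out, "n_patients_per_draw") <- n_patients_per_draw
  attr(out, "horizon") <- horizon
  class(out) <- c("sui_psa", class(out))
  out
}

# draws x strategies matrices of cost and qaly from a rectangular sample
psa_matrices <- function(sample) {
  df <- tibble::as_tibble(sample)
  strategies <- unique(df$strategy)
  draws <- sort(unique(df$draw))
  cost <- matrix(NA_real_, length(draws), length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (j in seq_along(strategies)) {
    sub <- df[df$strategy == strategies[j], ]
    sub <- sub[match(draws, sub$draw), ]
    cost[, j] <- sub$cost
    qaly[, j] <- sub$qaly
  }
  if (anyNA(cost) || anyNA(qaly)) {
    stop("sample is not rectangular: every draw must cover every strategy",
         call. = FALSE)
  }
  list(cost = cost, qaly = qaly, strategies = strategies)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the maximal net monetary benefit (`wtp * qaly - cost`) across
#' draws. Exact ties split their draw's probability equally, so the
#' probabilities sum to one at every threshold.
#'
#' @param sample A `sui_psa` sample (or any tibble with `draw`, `strategy`,
#'   `cost`, `qaly`).
#' @param wtp_grid Willingness-to-pay values (non-empty).
#' @return A `sui_ceac` tibble with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(sample, wtp_grid) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  m <- psa_matrices(sample)
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * m$qaly - m$cost
    mx <- apply(nmb, 1, max)
    ind <- (nmb == mx) * 1
    wts <- ind / rowSums(ind)
    tibble::tibble(wtp = w, strategy = m$strategies,
                   probability = unname(colMeans(wts)))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("sui_ceac", class(out))
  out
}

#' Per-person expected value of perfect information
#'
#' The expected gain from resolving all parameter uncertainty before
#' choosing a strategy: the mean over draws of the per-draw maximal net
#' monetary benefit, minus the net monetary benefit of the best strategy
#' on average. Non-negative by construction.
#'
#' @param sample A `sui_psa` sample.
#' @param wtp Willingness-to-pay per QALY.
#' @return EVPI per person, in the same currency as costs.
#' @export
evpi_per_person <- function(sample, wtp) {
  m <- psa_matrices(sample)
  nmb <- wtp * m$qaly - m$cost
  mean(apply(nmb, 1, max)) - max(colMeans(nmb))
}

#' Scale per-person EVPI to the affected population
#'
#' Multiplies the per-person value by the annual number of people affected
#' and the number of years the information would remain useful. The default
#' is the undiscounted product; with a positive discount rate the yearly
#' cohorts are discounted, `per_person * annual * sum((1+r)^-(0:(years-1)))`.
#'
#' @param per_person Per-person EVPI.
#' @param annual_affected People affected per year (15,000 in the base
#'   case).
#' @param years Number of years.
#' @param discount_rate Annual discount rate applied across years
#'   (default 0).
#' @return Population EVPI.
#' @export
#' @examples
#' population_evpi(11857, 15000, 10)
population_evpi <- function(per_person, annual_affected, years,
                            discount_rate = 0) {
  stopifnot(per_person >= 0, annual_affected >= 0, years >= 0,
            discount_rate >= 0)
  if (years == 0) return(0)
  if (discount_rate == 0) {
    per_person * annual_affected * years
  } else {
    per_person * annual_affected *
      sum((1 + discount_rate)^(-(seq_len(years) - 1)))
  }
}

#' Expected value of partial perfect information
#'
#' Single-loop regression estimator: each strategy's net monetary benefit
#' is regressed on the sampled values of the parameter group with an
#' additive spline smoother ([mgcv::gam()]); the fitted values estimate the
#' conditional expected net benefit given the group, and
#' \eqn{\mathrm{EVPPI} = \mathrm{mean}_d \max_s \hat{f}_s -
#' \max_s \mathrm{mean}_d \hat{f}_s}. The estimate is clamped to
#' `[0, EVPI]`, the analytic bounds.
#'
#' @param sample A `sui_psa` sample with a `parameters` attribute.
#' @param parameter_group Name of a recorded group (see `attr(sample,
#'   "groups")`), `"all"`, or a character vector of recorded parameter
#'   columns.
#' @param wtp Willingness-to-pay per QALY.
#' @return EVPPI for the group, in currency units.
#' @export
evppi <- function(sample, parameter_group, wtp) {
  params <- attr(sample, "parameters")
  if (is.null(params)) {
    stop("sample carries no sampled-parameter record", call. = FALSE)
  }
  groups <- attr(sample, "groups")
  cols <- if (length(parameter_group) == 1 && parameter_group == "all") {
    setdiff(names(params), "draw")
  } else if (length(parameter_group) == 1 && parameter_group %in% names(groups)) {
    groups[[parameter_group]]
  } else {
    parameter_group
  }
  missing <- setdiff(cols, names(params))
  if (length(missing) > 0 || length(cols) == 0) {
    stop("parameter group not recorded: ",
         paste(c(parameter_group[!parameter_group %in% names(groups)], missing),
               collapse = ", "),
         call. = FALSE)
  }
  m <- psa_matrices(sample)
  nmb <- wtp * m$qaly - m$cost
  X <- as.data.frame(params[, cols, drop = FALSE])
  # drop degenerate (constant) parameters; they carry no information
  keep <- vapply(X, function(x) stats::var(x) > 0, logical(1))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) return(0)
  names(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  k <- if (ncol(X) == 1) min(10, max(4, floor(n / 10))) else 4
  # spline smoothers need enough draws per basis; degrade gracefully to a
  # linear conditional-mean model on very small samples
  use_gam <- n >= 10 * ncol(X) && n >= 30
  fitted <- matrix(NA_real_, n, ncol(nmb))
  for (j in seq_len(ncol(nmb))) {
    dat <- cbind(data.frame(y = nmb[, j]), X)
    fit <- if (use_gam) {
      form <- stats::as.formula(paste(
        "y ~", paste(sprintf("s(%s, k = %d)", names(X), k), collapse = " + ")
      ))
      mgcv::gam(form, data = dat)
    } else {
      stats::lm(y ~ ., data = dat)
    }
    fitted[, j] <- stats::fitted(fit)
  }
  est <- mean(apply(fitted, 1, max)) - max(colMeans(fitted))
  min(max(est, 0), evpi_per_person(sample, wtp))
}

#' @rdname run_psa
#' @param x A `sui_psa` object.
#' @param ... Unused.
#' @method tidy sui_psa
#' @export
tidy.sui_psa <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      mean_cost = mean(.data$cost),
      mean_qaly = mean(.data$qaly),
      cost_lo = stats::quantile(.data$cost, 0.025),
      cost_hi = stats::quantile(.data$cost, 0.975),
      qaly_lo = stats::quantile(.data$qaly, 0.025),
      qaly_hi = stats::quantile(.data$qaly, 0.975),
      .groups = "drop"
    )
}

#' @rdname run_psa
#' @method glance sui_psa
#' @export
glance.sui_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = length(unique(x$draw)),
    n_strategies = length(unique(x$strategy)),
    n_patients_per_draw = attr(x, "n_patients_per_draw"),
    horizon = attr(x, "horizon"),
    seed = attr(x, "seed")
  )
}

#' Plot the cost-effectiveness plane of a PSA sample
#'
#' @param object A `sui_psa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sui_psa
#' @export
autoplot.sui_psa <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$qaly, y = .data$cost, colour = .data$strategy)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "Discounted QALYs", y = "Discounted cost (£)",
      colour = "Strategy", title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A `sui_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sui_ceac
#' @export
autoplot.sui_ceac <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$wtp, y = .data$probability,
                 colour = .data$strategy)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (£/QALY)",
      y = "Probability cost-effective",
      colour = "Strategy",
      title = "Cost-effectiveness acceptability curves"
    ) +
    ggplot2::theme_minimal()
}

#' Write / read a PSA sample as delimited text
#'
#' `write_psa()` stores the per-draw cost/QALY table (`psa_draws.csv`) and
#' the sampled-parameter sidecar (`psa_parameters.csv`) in `dir`;
#' `read_psa()` reconstructs the `sui_psa` object (parameter groups are
#' re-derived from the column-name prefixes), so value-of-information
#' analyses can be re-run without re-simulating.
#'
#' @param sample A `sui_psa` object.
#' @param dir Directory for the two files (created if needed).
#' @return `dir` (invisibly) for the writer; a `sui_psa` object for the
#'   reader.
#' @export
write_psa <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(tibble::as_tibble(sample)),
            file.path(dir, "psa_draws.csv"), row.names = FALSE, quote = FALSE)
  params <- attr(sample, "parameters")
  if (!is.null(params)) {
    write.csv(as.data.frame(params), file.path(dir, "psa_parameters.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_psa
#' @export
read_psa <- function(dir) {
  out <- tibble::as_tibble(read.csv(file.path(dir, "psa_draws.csv")))
  ppath <- file.path(dir, "psa_parameters.csv")
  if (file.exists(ppath)) {
    params <- tibble::as_tibble(read.csv(ppath, check.names = FALSE))
    attr(out, "parameters") <- params
    attr(out, "groups") <- default_parameter_groups(names(params))
  }
  class(out) <- c("sui_psa", class(out))
  out
}

#' Write a CEAC or value-of-information table as delimited text
#'
#' @param tab A tibble keyed by `wtp`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wtp_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
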