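# continence states: "awaiting" (incontinent, surgery pending or declined not
# yet resolved), "cured", "containment" (permanent pad/device management)

horizon_cycles <- function(p, horizon) {
  switch(horizon,
    "1y" = 12L,
    "10y" = 120L,
    "lifetime" = as.integer((100 - p$population$start_age) * 12),
    stop("horizon must be one of {1y, 10y, lifetime}; got '", horizon, "'",
         call. = FALSE)
  )
}

#' Compile a parameter set into a simulation context
#'
#' Precomputes everything the per-cycle engine needs: monthly mortality by
#' cycle (annual probabilities converted under a constant within-year
#' hazard, \eqn{q_m = 1-(1-q_a)^{1/12}}), cure probabilities per strategy
#' and surgery number, the Weibull conditional recurrence schedule,
#' per-strategy complication vectors, mid-cycle discount factors and state
#' utilities. Cycle length is fixed at one month.
#'
#' Recurrence risk starts at the 12-month cure-assessment point: a cured
#' woman faces no recurrence draw during the first 12 months after surgery,
#' then the conditional Weibull hazard applies, so the cured fraction at 1
#' and 5 years reproduces the fitted anchors exactly in expectation.
#'
#' @param p A `sui_parameters` object (optionally a sampled realisation).
#' @param horizon `"1y"`, `"10y"` or `"lifetime"` (to death or age 100).
#' @param or Optional named vector of cure odds ratios per strategy
#'   (e.g. one probabilistic draw); defaults to the median estimates.
#' @return A `sui_model` context consumed by [step_cycle()],
#'   [simulate_patient()] and [simulate_cohort()].
#' @export
compile_model <- function(p, horizon, or = NULL) {
  stopifnot(inherits(p, "sui_parameters"))
  n_cycles <- horizon_cycles(p, horizon)
  start_age <- p$population$start_age
  lt <- p$life_table

  ages <- start_age + (seq_len(n_cycles) - 1L) %/% 12L
  idx <- pmin(pmax(ages, min(lt$age)), max(lt$age)) - min(lt$age) + 1L
  qx <- lt$qx[idx]
  mort <- ifelse(qx >= 1, 1, 1 - (1 - qx)^(1 / 12))

  sid <- p$strategies$id
  if (is.null(or)) {
    or <- setNames(rep(1, length(sid)), sid)
    for (s in p$effects$strategy) {
      or[s] <- p$effects$or_median[p$effects$strategy == s]
    }
  }
  cure1 <- setNames(
    vapply(sid, function(s) effective_cure_prob(p, s, 1, or = or[[s]]),
           numeric(1)),
    sid
  )
  cure_re <- setNames(
    vapply(c("retro-MUS", "transob-MUS"),
           function(s) effective_cure_prob(p, s, 2, or = or[[s]]),
           numeric(1)),
    c("retro-MUS", "transob-MUS")
  )

  # conditional recurrence per month since surgery; no risk before the
  # 12-month assessment point. A boundary 12-month cure proportion (>= 1)
  # degenerates to no recurrence at all.
  cure12 <- p$baseline_cure$cure_prop[p$baseline_cure$time_months == 12L]
  cure60 <- p$baseline_cure$cure_prop[p$baseline_cure$time_months == 60L]
  if (cure12 >= 1) {
    w <- NULL
    rec <- rep(0, n_cycles + 13L)
  } else {
    w <- fit_weibull_two_points(1, cure12, 5, cure60)
    m <- 0:(n_cycles + 12L)
    rec <- ifelse(m < 12L, 0, cycle_recurrence_prob(w, m / 12, 1 / 12))
  }

  comp_names <- unique(p$complications$name)
  comp <- lapply(sid, function(s) {
    rows <- p$complications[p$complications$strategy == s, ]
    m <- match(comp_names, rows$name)
    list(
      inc = ifelse(is.na(m), 0, rows$incidence[m]),
      cost = ifelse(is.na(m), 0, rows$one_off_cost[m]),
      decr = ifelse(is.na(m), 0, rows$utility_decrement[m]),
      dur = as.integer(ifelse(is.na(m), 0L, rows$duration_cycles[m])),
      uui = ifelse(is.na(m), FALSE, rows$triggers_uui[m])
    )
  })
  names(comp) <- sid

  r <- p$economics$discount_rate_annual
  disc <- (1 + r)^(-(seq_len(n_cycles) - 0.5) / 12)

  uval <- setNames(p$utilities$value, p$utilities$name)
  uu <- p$uui_pathway[order(p$uui_pathway$line), ]

  structure(list(
    params = p,
    horizon = horizon,
    n_cycles = n_cycles,
    start_age = start_age,
    mort = mort,
    cure1 = cure1,
    cure_re = cure_re,
    weibull = w,
    rec = rec,
    comp_names = comp_names,
    comp = comp,
    proc_cost = setNames(
      p$costs$procedure$cost[match(sid, p$costs$procedure$strategy)], sid
    ),
    followup = p$costs$followup_per_surgery,
    containment_cost = p$costs$containment_per_cycle,
    uui_cost = uu$cost,
    uui_succ = uu$success_prob,
    uui_dur = as.integer(uu$duration_cycles),
    disc = disc,
    u_pre = uval[["u_pre_treatment_sui"]],
    u_cured = uval[["u_cured"]],
    u_containment = uval[["u_containment"]],
    u_uui = uval[["u_uui"]],
    retreat = p$retreatment,
    p_uui_baseline = p$population$p_uui_baseline
  ), class = "sui_model")
}

#' Initialise a patient state
#'
#' A woman enters the model incontinent, with her assigned surgery
#' scheduled for the first cycle. Whether she also has urge incontinence
#' (stress-predominant mixed incontinence) is drawn here with probability
#' `p_uui_baseline`.
#'
#' @param ctx A `sui_model` context from [compile_model()].
#' @param strategy Strategy id of the initial surgery.
#' @return A patient-state list consumed and returned by [step_cycle()].
#' @export
new_patient <- function(ctx, strategy) {
  if (!strategy %in% names(ctx$cure1)) {
    stop("unknown strategy: ", strategy, call. = FALSE)
  }
  list(
    cycle = 1L,
    alive = TRUE,
    continence = "awaiting",
    pending_surgery = strategy,
    surgeries_done = 0L,
    months_since_surgery = NA_integer_,
    comp_rem = integer(length(ctx$comp_names)),
    decr_active = numeric(length(ctx$comp_names)),
    uui = runif(1) < ctx$p_uui_baseline,
    uui_line = 0L, # 0 untreated, 1..3 on that line, 4 exhausted
    uui_rem = 0L,
    c_surgery = 0, c_followup = 0, c_containment = 0,
    c_uui = 0, c_complication = 0,
    qaly = 0
  )
}

#' Advance a patient by one monthly cycle
#'
#' Applies, in fixed order: (1) all-cause mortality by current age;
#' (2) any scheduled surgery — cure determination and complication onset
#' draws; (3) Weibull conditional recurrence for cured women (from the
#' 12-month assessment point onward); (4) re-treatment seeking after a
#' failure (75% after the first, 30% after the second, with the replacement
#' surgery drawn 55/45 retropubic/transobturator), containment otherwise
#' and always after the third failure; (5) urge-incontinence treatment-line
#' progression (bladder training, medication, botulinum toxin);
#' (6) complication-duration bookkeeping; (7) accrual of this cycle's cost
#' and utility, discounted at mid-cycle. A woman who dies in a cycle
#' accrues nothing in that cycle, and stepping a dead patient is an error.
#'
#' @param state A patient state from [new_patient()] or a previous step.
#' @param ctx A `sui_model` context.
#' @return The updated state, with `cycle` advanced by one.
#' @export
step_cycle <- function(state, ctx) {
  if (!state$alive) stop("cannot step a dead patient", call. = FALSE)
  t <- state$cycle
  if (t > ctx$n_cycles) {
    stop("cycle ", t, " is beyond the simulation horizon", call. = FALSE)
  }
  d <- ctx$disc[t]

  # (1) all-cause mortality; death is absorbing, no accrual this cycle
  if (runif(1) < ctx$mort[t]) {
    state$alive <- FALSE
    state$cycle <- t + 1L
    return(state)
  }

  newly_failed <- FALSE

  # (2) scheduled surgery: costs, cure determination, complication onset
  if (!is.na(state$pending_surgery)) {
    s <- state$pending_surgery
    state$pending_surgery <- NA_character_
    state$surgeries_done <- state$surgeries_done + 1L
    state$c_surgery <- state$c_surgery + ctx$proc_cost[[s]] * d
    state$c_followup <- state$c_followup + ctx$followup * d
    pcure <- if (state$surgeries_done == 1L) ctx$cure1[[s]] else ctx$cure_re[[s]]
    if (runif(1) < pcure) {
      state$continence <- "cured"
      state$months_since_surgery <- 0L
    } else {
      newly_failed <- TRUE
    }
    cp <- ctx$comp[[s]]
    for (k in seq_along(cp$inc)) {
      if (cp$inc[k] > 0 && runif(1) < cp$inc[k]) {
        state$c_complication <- state$c_complication + cp$cost[k] * d
        state$comp_rem[k] <- max(state$comp_rem[k], cp$dur[k])
        state$decr_active[k] <- max(state$decr_active[k], cp$decr[k])
        if (cp$uui[k] && !state$uui && state$uui_line < 4L) {
          state$uui <- TRUE
          state$uui_line <- 0L
          state$uui_rem <- 0L
        }
      }
    }
  } else if (state$continence == "cured") {
    # (3) conditional recurrence for women cured in an earlier cycle
    pr <- ctx$rec[state$months_since_surgery + 1L]
    if (pr > 0 && runif(1) < pr) {
      state$continence <- "awaiting"
      state$months_since_surgery <- NA_integer_
      newly_failed <- TRUE
    }
  }

  # (4) re-treatment seeking after a failure event
  if (newly_failed) {
    nf <- state$surgeries_done # failure of the nf-th surgery
    if (nf >= ctx$retreat$max_surgeries) {
      state$continence <- "containment"
    } else {
      p_seek <- if (nf == 1L) ctx$retreat$p_seek_first_retreat
                else ctx$retreat$p_seek_second_retreat
      if (runif(1) < p_seek) {
        state$continence <- "awaiting"
        state$pending_surgery <- if (runif(1) < ctx$retreat$retreat_mix_retro)
          "retro-MUS" else "transob-MUS"
      } else {
        state$continence <- "containment"
      }
    }
  }

  # (5) urge-incontinence treatment ladder
  if (state$uui && state$uui_line < 4L) {
    if (state$uui_line == 0L) {
      state$uui_line <- 1L
      state$uui_rem <- ctx$uui_dur[1]
      state$c_uui <- state$c_uui + ctx$uui_cost[1] * d
    } else {
      state$uui_rem <- state$uui_rem - 1L
      if (state$uui_rem <= 0L) {
        if (runif(1) < ctx$uui_succ[state$uui_line]) {
          state$uui <- FALSE
        } else if (state$uui_line < 3L) {
          state$uui_line <- state$uui_line + 1L
          state$uui_rem <- ctx$uui_dur[state$uui_line]
          state$c_uui <- state$c_uui + ctx$uui_cost[state$uui_line] * d
        } else {
          state$uui_line <- 4L
        }
      }
    }
  }

  # (6) complication durations: this cycle counts as active, then decrement
  decr <- 0
  if (any(state$comp_rem > 0L)) {
    decr <- sum(state$decr_active[state$comp_rem > 0L])
    state$comp_rem <- pmax(state$comp_rem - 1L, 0L)
  }

  # (7) cost/utility accrual with mid-cycle discounting
  base <- if (state$uui) ctx$u_uui
          else if (state$continence == "cured") ctx$u_cured
          else if (state$continence == "containment") ctx$u_containment
          else ctx$u_pre
  state$qaly <- state$qaly + max(0, base - decr) / 12 * d
  if (state$continence == "containment") {
    state$c_containment <- state$c_containment + ctx$containment_cost * d
  }

  state$cycle <- t + 1L
  if (state$continence == "cured") {
    state$months_since_surgery <- state$months_since_surgery + 1L
  }
  state
}

#' Simulate one woman through the treatment pathway
#'
#' Runs [step_cycle()] from the initial surgery until death or the horizon,
#' returning her discounted totals. With a fixed `seed` the result is
#' bit-identical on re-run.
#'
#' @param p A `sui_parameters` object or a precompiled `sui_model` context.
#' @param strategy Strategy id of the initial surgery (ignored if `p` is a
#'   compiled context only in the sense that it must still be supplied).
#' @param horizon `"1y"`, `"10y"` or `"lifetime"` (ignored when `p` is
#'   already compiled).
#' @param seed Optional integer seed for this patient's draws.
#' @param trace If `TRUE`, attach a per-cycle trajectory tibble as the
#'   `trace` attribute (columns: cycle, age, alive, continence,
#'   surgeries_done, uui, pending_surgery).
#' @return A one-row tibble: `cost`, `qaly` (discounted totals), the cost
#'   components (`c_surgery`, `c_followup`, `c_containment`, `c_uui`,
#'   `c_complication`), `n_surgeries`, `final_state`, `containment` (flag),
#'   `death_cycle` (`NA` if alive at the horizon).
#' @export
#' @examples
#' p <- default_parameters()
#' simulate_patient(p, "retro-MUS", "1y", seed = 1)
simulate_patient <- function(p, strategy, horizon = "lifetime", seed = NULL,
                             trace = FALSE) {
  ctx <- if (inherits(p, "sui_model")) p else compile_model(p, horizon)
  if (!is.null(seed)) set.seed(seed)
  state <- new_patient(ctx, strategy)
  log <- if (trace) vector("list", ctx$n_cycles) else NULL
  while (state$alive && state$cycle <= ctx$n_cycles) {
    state <- step_cycle(state, ctx)
    if (trace) {
      log[[state$cycle - 1L]] <- tibble::tibble(
        cycle = state$cycle - 1L,
        age = ctx$start_age + (state$cycle - 2L) %/% 12L,
        alive = state$alive,
        continence = state$continence,
        surgeries_done = state$surgeries_done,
        uui = state$uui,
        pending_surgery = state$pending_surgery
      )
    }
  }
  out <- patient_summary(state, ctx)
  if (trace) {
    attr(out, "trace") <- dplyr::bind_rows(log[!vapply(log, is.null, logical(1))])
  }
  out
}

patient_summary <- function(state, ctx) {
  cost <- state$c_surgery + state$c_followup + state$c_containment +
    state$c_uui + state$c_complication
  tibble::tibble(
    cost = cost,
    qaly = state$qaly,
    c_surgery = state$c_surgery,
    c_followup = state$c_followup,
    c_containment = state$c_containment,
    c_uui = state$c_uui,
    c_complication = state$c_complication,
    n_surgeries = state$surgeries_done,
    final_state = state$continence,
    containment = state$continence == "containment",
    death_cycle = if (state$alive) NA_integer_ else state$cycle - 1L
  )
}

#' Simulate a cohort under one strategy
#'
#' Simulates `n` independent women, each on her own deterministic
#' random-number substream derived from `seed` and her index, so results do
#' not depend on execution order and the same patient substreams are reused
#' across strategies (common random numbers).
#'
#' @param p A `sui_parameters` object or compiled `sui_model` context.
#' @param strategy Strategy id.
#' @param n Number of simulated women.
#' @param horizon `"1y"`, `"10y"` or `"lifetime"`.
#' @param seed Integer seed for the cohort.
#' @param keep_patients If `TRUE`, attach the per-patient tibble as the
#'   `patients` attribute.
#' @return A one-row tibble: `strategy`, `horizon`, `n`, `mean_cost`,
#'   `se_cost`, `mean_qaly`, `se_qaly`.
#' @export
#' @examples
#' p <- default_parameters()
#' simulate_cohort(p, "retro-MUS", n = 50, horizon = "1y", seed = 1)
simulate_cohort <- function(p, strategy, n, horizon = "lifetime", seed = 1,
                            keep_patients = FALSE) {
  stopifnot(n >= 1)
  ctx <- if (inherits(p, "sui_model")) p else compile_model(p, horizon)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- simulate_patient(ctx, strategy, seed = substream_seed(seed, i))
  }
  patients <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    strategy = strategy,
    horizon = ctx$horizon,
    n = n,
    mean_cost = mean(patients$cost),
    se_cost = stats::sd(patients$cost) / sqrt(n),
    mean_qaly = mean(patients$qaly),
    se_qaly = stats::sd(patients$qaly) / sqrt(n)
  )
  if (keep_patients) attr(out, "patients") <- patients
  out
}
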