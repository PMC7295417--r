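# Fixture builders shared across test files. All fixtures are constructed in
# code from the default parameter set; nothing is read from disk.

# Degenerate two-state (cured/dead) configuration: everyone is cured at the
# first surgery, no recurrence, no complications, no urge incontinence, a
# flat annual mortality probability, and a single state utility. Mean
# discounted QALYs then follow a geometric series in the monthly survival
# and discount factors.
two_state_parameters <- function(annual_q = 0.02, discount = 0.035,
                                 utility = 0.85) {
  p <- default_parameters()
  p$complications$incidence[] <- 0
  p$population$p_uui_baseline <- 0
  p$baseline_cure$cure_prop[p$baseline_cure$time_months == 12L] <- 1
  p$life_table <- tibble::tibble(age = 40:100, qx = annual_q)
  p$utilities$value[p$utilities$name == "u_cured"] <- utility
  p$economics$discount_rate_annual <- discount
  p$costs$containment_per_cycle <- 0
  p
}

# closed-form mean discounted QALY for the two-state configuration over T
# monthly cycles, under the engine's conventions (mortality checked at the
# start of each cycle, survivors accrue utility/12 at mid-cycle)
two_state_expected_qaly <- function(annual_q, discount, utility, T) {
  s <- (1 - annual_q)^(1 / 12)
  d <- (1 + discount)^(-1 / 12)
  t <- seq_len(T)
  utility / 12 * sum(s^t * d^(t - 0.5))
}

# High-failure configuration: almost nobody is cured and everyone seeks
# re-treatment, driving trajectories through all three surgeries and into
# containment. Mortality is kept low so pathways play out.
forced_failure_parameters <- function() {
  p <- default_parameters()
  p$baseline_cure$cure_prop[p$baseline_cure$time_months == 12L] <- 0.05
  p$baseline_cure$cure_prop[p$baseline_cure$time_months == 60L] <- 0.01
  p$retreatment$p_seek_first_retreat <- 1
  p$retreatment$p_seek_second_retreat <- 1
  p$life_table$qx[] <- 0.001
  p$life_table$qx[nrow(p$life_table)] <- 1
  p
}

# hand-made rectangular PSA sample from a draws x strategies NMB matrix,
# realised at wtp = 1 with zero costs (so nmb == qaly)
nmb_sample <- function(nmb, strategies = paste0("S", seq_len(ncol(nmb)))) {
  out <- tidyr::expand_grid(
    draw = seq_len(nrow(nmb)),
    strategy = strategies
  )
  out$cost <- 0
  out$qaly <- as.vector(t(nmb))
  class(out) <- c("sui_psa", class(out))
  out
}
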