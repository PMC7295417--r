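test_that("an immortal cured woman accrues an exact discounted series", {
  # no mortality, cure certain at the first surgery, no other events: the
  # QALY total is a deterministic geometric series, no Monte Carlo error
  p <- two_state_parameters(annual_q = 0, discount = 0.035, utility = 0.85)
  r <- simulate_patient(p, "retro-MUS", "10y", seed = 1)
  expect_equal(r$qaly, two_state_expected_qaly(0, 0.035, 0.85, 120),
               tolerance = 1e-12)
  # cost is the discounted procedure + follow-up only
  d1 <- (1.035)^(-0.5 / 12)
  expect_equal(r$cost, (1400 + 350) * d1, tolerance = 1e-12)
  expect_identical(r$n_surgeries, 1L)
  expect_true(is.na(r$death_cycle))

  # undiscounted degenerate check: one year of utility 0.8
  p0 <- two_state_parameters(annual_q = 0, discount = 0, utility = 0.8)
  r0 <- simulate_patient(p0, "retro-MUS", "1y", seed = 1)
  expect_equal(r0$qaly, 0.8, tolerance = 1e-12)
})

test_that("certain first-cycle death is absorbing with zero accrual", {
  p <- two_state_parameters(annual_q = 1)
  r <- simulate_patient(p, "retro-MUS", "10y", seed = 1)
  expect_identical(r$death_cycle, 1L)
  expect_equal(r$qaly, 0)
  expect_equal(r$cost, 0)
  expect_identical(r$n_surgeries, 0L)
  # stepping a dead patient raises
  ctx <- compile_model(p, "1y")
  set.seed(1)
  st <- step_cycle(new_patient(ctx, "retro-MUS"), ctx)
  expect_false(st$alive)
  expect_error(step_cycle(st, ctx), "dead")
})

test_that("fixed seeds reproduce bit-identical results", {
  p <- default_parameters()
  a <- simulate_patient(p, "transob-MUS", "10y", seed = 99)
  b <- simulate_patient(p, "transob-MUS", "10y", seed = 99)
  expect_identical(a, b)
  ca <- simulate_cohort(p, "trad-sling", n = 30, horizon = "1y", seed = 5)
  cb <- simulate_cohort(p, "trad-sling", n = 30, horizon = "1y", seed = 5)
  expect_identical(ca, cb)
})

test_that("shorter horizons accrue no more than longer ones on one stream", {
  p <- default_parameters()
  for (seed in c(2, 17, 31)) {
    r1 <- simulate_patient(p, "retro-MUS", "1y", seed = seed)
    r10 <- simulate_patient(p, "retro-MUS", "10y", seed = seed)
    expect_lte(r1$qaly, r10$qaly)
    expect_lte(r1$cost, r10$cost)
  }
})

test_that("a cohort of one equals the patient on its substream", {
  p <- default_parameters()
  co <- simulate_cohort(p, "open-colpo", n = 1, horizon = "1y", seed = 3)
  pt <- simulate_patient(p, "open-colpo", "1y",
                         seed = suicea:::substream_seed(3, 1))
  expect_equal(co$mean_cost, pt$cost)
  expect_equal(co$mean_qaly, pt$qaly)
})

test_that("microsimulation agrees with the two-state closed form", {
  q_a <- 0.06
  p <- two_state_parameters(annual_q = q_a, discount = 0.035, utility = 0.85)
  n <- 4000
  co <- simulate_cohort(p, "retro-MUS", n = n, horizon = "10y", seed = 42)
  expected <- two_state_expected_qaly(q_a, 0.035, 0.85, 120)
  expect_lt(abs(co$mean_qaly - expected), 3 * co$se_qaly)
})

test_that("standard errors shrink like one over root n", {
  p <- default_parameters()
  se1 <- simulate_cohort(p, "retro-MUS", n = 150, horizon = "1y",
                         seed = 1)$se_qaly
  se4 <- simulate_cohort(p, "retro-MUS", n = 600, horizon = "1y",
                         seed = 1)$se_qaly
  expect_lt(abs(se4 / se1 - 0.5), 0.2)
})

test_that("costs decompose exactly and complications can be switched off", {
  p <- default_parameters()
  p$complications$incidence[] <- 0
  co <- simulate_cohort(p, "retro-MUS", n = 120, horizon = "10y", seed = 8,
                        keep_patients = TRUE)
  pats <- attr(co, "patients")
  expect_true(all(pats$c_complication == 0))
  expect_equal(
    pats$cost,
    pats$c_surgery + pats$c_followup + pats$c_containment + pats$c_uui,
    tolerance = 1e-12
  )
  # and with the urge-incontinence pathway also off, no UUI costs either
  p$population$p_uui_baseline <- 0
  co2 <- simulate_cohort(p, "retro-MUS", n = 120, horizon = "10y", seed = 8,
                         keep_patients = TRUE)
  expect_true(all(attr(co2, "patients")$c_uui == 0))
})

test_that("no trajectory exceeds three surgeries; third failure means containment", {
  p <- forced_failure_parameters()
  co <- simulate_cohort(p, "retro-MUS", n = 400, horizon = "10y", seed = 21,
                        keep_patients = TRUE)
  pats <- attr(co, "patients")
  expect_lte(max(pats$n_surgeries), 3L)
  # with cure prob 0.05 and certain seeking, almost everyone burns through
  # all three surgeries; after a third failure the only non-absorbing state
  # left is containment (survivors are either still cured or contained)
  three <- pats[pats$n_surgeries == 3L & is.na(pats$death_cycle), ]
  expect_gt(nrow(three), 200)
  expect_true(all(three$final_state %in% c("cured", "containment")))
  expect_gt(mean(three$containment), 0.8)

  # trace-level check: once in containment, never again awaiting or operated
  for (seed in 1:25) {
    tr <- attr(
      simulate_patient(p, "retro-MUS", "10y",
                       seed = seed, trace = TRUE),
      "trace"
    )
    expect_lte(max(tr$surgeries_done), 3L)
    first_cont <- match("containment", tr$continence)
    if (!is.na(first_cont)) {
      after <- tr[tr$cycle >= first_cont, ]
      expect_true(all(after$continence == "containment" | !after$alive))
      expect_identical(unique(after$surgeries_done),
                       tr$surgeries_done[first_cont])
    }
  }
})

test_that("unknown horizons and strategies are rejected", {
  p <- default_parameters()
  expect_error(simulate_patient(p, "retro-MUS", "2y"), "1y, 10y, lifetime")
  expect_error(simulate_patient(p, "nope", "1y"), "unknown strategy")
})
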