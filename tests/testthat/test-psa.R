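degenerate_distributions <- function(p) {
  p$effects$crl_low <- p$effects$or_median
  p$effects$crl_high <- p$effects$or_median
  p$complications$ess <- Inf
  p$utilities$ess <- Inf
  p$costs$cost_cv <- 0
  p
}

test_that("degenerate uncertainty specifications pass means through exactly", {
  p <- degenerate_distributions(default_parameters())
  set.seed(1)
  ps <- sample_parameter_set(p)
  expect_equal(unclass(ps), unclass(p), ignore_attr = TRUE)
  rec <- attr(ps, "psa_record")
  expect_equal(rec[["or.transob-MUS"]], 0.738)
  expect_equal(rec[["util.u_cured"]], 0.85)
})

test_that("sampled parameters recover their specification", {
  p <- default_parameters()
  set.seed(5)
  n <- 2000
  recs <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    r <- attr(sample_parameter_set(p), "psa_record")
    recs[i, ] <- c(r[["or.transob-MUS"]], r[["cinc.infection.retro-MUS"]],
                   r[["util.u_cured"]], r[["cost.proc.retro-MUS"]])
  }
  # lognormal median, beta means, gamma mean, each within 3 SE
  expect_lt(abs(median(recs[, 1]) - 0.738),
            3 * 1.2533 * stats::sd(recs[, 1]) / sqrt(n))
  expect_lt(abs(mean(recs[, 2]) - 0.03), 3 * stats::sd(recs[, 2]) / sqrt(n))
  expect_lt(abs(mean(recs[, 3]) - 0.85), 3 * stats::sd(recs[, 3]) / sqrt(n))
  expect_lt(abs(mean(recs[, 4]) - 1400), 3 * stats::sd(recs[, 4]) / sqrt(n))
  expect_true(all(recs > 0))
})

test_that("invalid uncertainty specifications raise at sampling time", {
  p <- default_parameters()
  p$complications$ess[1] <- -5
  expect_error(sample_parameter_set(p), "effective sample size")
  p2 <- default_parameters()
  p2$costs$cost_cv <- -0.1
  expect_error(sample_parameter_set(p2), "coefficient of variation")
})

test_that("the probabilistic analysis is reproducible and rectangular", {
  p <- default_parameters()
  a <- run_psa(p, n_draws = 3, n_patients_per_draw = 5, horizon = "1y",
               seed = 11)
  b <- run_psa(p, n_draws = 3, n_patients_per_draw = 5, horizon = "1y",
               seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(nrow(a), 27L) # 3 draws x 9 strategies
  expect_true(all(a$cost >= 0))
  params <- attr(a, "parameters")
  expect_identical(nrow(params), 3L)
  expect_true(all(c("or.transob-MUS", "util.u_cured") %in% names(params)))
  expect_error(run_psa(p, n_draws = 1, n_patients_per_draw = 5), "at least 2")
})

test_that("with degenerate distributions every draw equals the base case", {
  p <- degenerate_distributions(default_parameters())
  s <- run_psa(p, n_draws = 3, n_patients_per_draw = 10, horizon = "1y",
               seed = 2)
  for (st in unique(s$strategy)) {
    expect_identical(length(unique(s$cost[s$strategy == st])), 1L)
    expect_identical(length(unique(s$qaly[s$strategy == st])), 1L)
  }
})

test_that("acceptability curves match brute-force enumeration and sum to one", {
  # 3 draws x 2 strategies decided by hand at wtp 20,000:
  # draw 1: A nmb 20000*1.0-1000=19000, B 20000*0.9-500 =17500 -> A
  # draw 2: A 20000*0.8-1000=15000,     B 20000*0.9-500 =17500 -> B
  # draw 3: A 20000*1.1-1000=21000,     B 20000*1.2-3500=20500 -> A
  sample <- tibble::tibble(
    draw = rep(1:3, each = 2),
    strategy = rep(c("A", "B"), 3),
    cost = c(1000, 500, 1000, 500, 1000, 3500),
    qaly = c(1.0, 0.9, 0.8, 0.9, 1.1, 1.2)
  )
  cc <- ceac(sample, 20000)
  expect_equal(cc$probability[cc$strategy == "A"], 2 / 3)
  expect_equal(cc$probability[cc$strategy == "B"], 1 / 3)

  # exact ties split equally
  tied <- tibble::tibble(
    draw = rep(1:2, each = 2), strategy = rep(c("A", "B"), 2),
    cost = 0, qaly = 1
  )
  ct <- ceac(tied, c(0, 10000))
  expect_true(all(ct$probability == 0.5))

  # normalisation across a grid on a simulated sample
  p <- default_parameters()
  s <- run_psa(p, n_draws = 4, n_patients_per_draw = 5, horizon = "1y",
               seed = 3)
  cs <- ceac(s, seq(0, 50000, by = 10000))
  sums <- as.numeric(tapply(cs$probability, cs$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_error(ceac(s, numeric(0)), "non-empty")

  # dominance: a strategy cheaper and more effective in every draw
  dom <- tibble::tibble(
    draw = rep(1:3, each = 2), strategy = rep(c("A", "B"), 3),
    cost = rep(c(100, 200), 3), qaly = rep(c(2, 1), 3)
  )
  cd <- ceac(dom, c(0, 20000, 50000))
  expect_true(all(cd$probability[cd$strategy == "A"] == 1))
})

test_that("per-person EVPI matches the two-draw brute force and its bounds", {
  s <- nmb_sample(matrix(c(10, 5, 4, 8), nrow = 2, byrow = TRUE))
  expect_equal(evpi_per_person(s, 1), 2)
  # identical strategies, and one strategy dominant in every draw -> 0
  expect_equal(evpi_per_person(nmb_sample(matrix(c(3, 3, 7, 7), 2)), 1), 0)
  expect_equal(evpi_per_person(nmb_sample(matrix(c(9, 1, 8, 2), 2,
                                                 byrow = TRUE)), 1), 0)
  # invariance under adding a constant to every strategy in every draw
  m <- matrix(runif(20), 5, 4)
  expect_equal(evpi_per_person(nmb_sample(m), 1),
               evpi_per_person(nmb_sample(m + 123.45), 1),
               tolerance = 1e-9)
})

test_that("population scaling reproduces exact multiples and discounts", {
  expect_identical(population_evpi(11857, 15000, 1), 177855000)
  expect_identical(population_evpi(11857, 15000, 10), 1778550000)
  expect_identical(population_evpi(123, 15000, 0), 0)
  expect_equal(population_evpi(100, 1000, 3, discount_rate = 0.035),
               100 * 1000 * (1 + 1 / 1.035 + 1 / 1.035^2))
})

test_that("regression EVPPI respects its limits on a linear toy", {
  set.seed(31)
  n <- 10000
  theta <- runif(n)
  noise <- rnorm(n)
  w <- 20000
  sample <- tibble::tibble(
    draw = rep(seq_len(n), each = 2),
    strategy = rep(c("A", "B"), n),
    cost = 0,
    qaly = as.vector(rbind(theta, 1 - theta))
  )
  class(sample) <- c("sui_psa", class(sample))
  attr(sample, "parameters") <- tibble::tibble(
    draw = seq_len(n), theta = theta, noise = noise
  )
  attr(sample, "groups") <- list(theta = "theta", noise = "noise")

  evpi <- evpi_per_person(sample, w)
  # closed form: E max(theta, 1-theta) = 3/4, best-on-average = 1/2
  expect_equal(evpi, w * 0.25, tolerance = 0.02 * w * 0.25)
  # theta carries all the decision uncertainty
  expect_equal(evppi(sample, "theta", w), w * 0.25,
               tolerance = 0.05 * w * 0.25)
  # an irrelevant parameter carries none
  expect_lt(evppi(sample, "noise", w), 0.05 * evpi)
  # the full parameter set recovers the EVPI
  expect_equal(evppi(sample, "all", w), evpi, tolerance = 0.05 * evpi)
  expect_error(evppi(sample, "unrecorded-group", w), "not recorded")
})

test_that("PSA samples round-trip through the text writer", {
  p <- default_parameters()
  s <- run_psa(p, n_draws = 3, n_patients_per_draw = 4, horizon = "1y",
               seed = 4)
  dir <- withr::local_tempdir()
  write_psa(s, dir)
  expect_true(file.exists(file.path(dir, "psa_draws.csv")))
  s2 <- read_psa(dir)
  expect_equal(as.data.frame(tibble::as_tibble(s2)),
               as.data.frame(tibble::as_tibble(s)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(
    as.data.frame(attr(s2, "parameters")),
    as.data.frame(attr(s, "parameters")),
    tolerance = 1e-9
  )
  # value-of-information analyses re-run from the file alone
  expect_equal(evpi_per_person(s2, 20000), evpi_per_person(s, 20000),
               tolerance = 1e-6)
})
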