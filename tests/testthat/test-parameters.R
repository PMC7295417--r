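cfg_path <- system.file("extdata", "default_config.yaml", package = "suicea")

test_that("shipped configuration loads with the published estimates intact", {
  p <- load_parameters(cfg_path)
  expect_s3_class(p, "sui_parameters")
  expect_equal(nrow(p$strategies), 9)
  expect_identical(p$strategies$id[p$strategies$reference], "retro-MUS")
  tr <- p$effects[p$effects$strategy == "transob-MUS", ]
  expect_equal(tr$or_median, 0.738)
  expect_equal(tr$crl_low, 0.588)
  expect_equal(tr$crl_high, 0.923)
  expect_equal(
    p$baseline_cure$cure_prop[p$baseline_cure$time_months == 12L], 0.841
  )
  prov <- attr(p, "provenance")
  expect_true(all(prov$provenance %in%
                    c("paper", "synthetic-default", "user")))
})

test_that("loading round-trips through serialisation field-for-field", {
  p <- default_parameters()
  dir <- withr::local_tempdir()
  write_parameters(p, file.path(dir, "cfg.yaml"))
  p2 <- load_parameters(file.path(dir, "cfg.yaml"))
  expect_equal(unclass(p2), unclass(p), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("schema errors name the offending field", {
  raw <- yaml::read_yaml(cfg_path)
  dir <- withr::local_tempdir()
  file.copy(system.file("extdata", "life_table.csv", package = "suicea"),
            file.path(dir, "life_table.csv"))

  broken <- raw
  broken$life_table <- NULL
  yaml::write_yaml(broken, file.path(dir, "no_lt.yaml"))
  expect_error(load_parameters(file.path(dir, "no_lt.yaml")), "life_table")

  broken <- raw
  broken$baseline_cure[[2]]$cure_prop <- "not-a-number"
  yaml::write_yaml(broken, file.path(dir, "bad_num.yaml"))
  expect_error(load_parameters(file.path(dir, "bad_num.yaml")),
               "cure_prop")

  expect_error(load_parameters(file.path(dir, "absent.yaml")), "not found")
})

test_that("validation returns every violation without raising", {
  expect_identical(nrow(validate_parameters(default_parameters())), 0L)

  p <- default_parameters()
  p$retreatment$retreat_mix_retro <- 0.6
  p$retreatment$retreat_mix_transob <- 0.45
  v <- validate_parameters(p)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "mix-sum")

  p <- default_parameters()
  p$complications$utility_decrement[1] <- 1.5
  v <- validate_parameters(p)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "decrement-range")

  p <- default_parameters()
  p$strategies$setting[p$strategies$id == "trad-sling"] <- "day-case"
  expect_true("setting" %in% validate_parameters(p)$rule)

  p <- default_parameters()
  p$economics$wtp_grid <- c(0, 10000, 25000)
  expect_true("wtp-thresholds" %in% validate_parameters(p)$rule)

  p <- default_parameters()
  p$life_table <- p$life_table[p$life_table$age >= 47, ]
  expect_true("start" %in% validate_parameters(p)$rule)
})

test_that("scenarios modify a copy, log themselves and are idempotent", {
  p <- default_parameters()

  q <- apply_scenario(p, list(mesh_incidence = 0.2))
  mus <- q$complications$name == "mesh-removal" &
    q$complications$strategy %in% c("retro-MUS", "transob-MUS")
  expect_true(all(q$complications$incidence[mus] == 0.2))
  # everything else identical, original untouched
  expect_equal(q$complications$incidence[!mus],
               p$complications$incidence[!mus])
  expect_false(any(p$complications$incidence == 0.2 &
                     p$complications$name == "mesh-removal"))
  expect_identical(attr(q, "scenario"), list(mesh_incidence = 0.2))

  q5 <- apply_scenario(p, list(persistent_pain_duration_years = 5))
  expect_true(all(q5$complications$duration_cycles[
    q5$complications$name == "persistent-pain"] == 60L))

  # identity and idempotence
  expect_equal(unclass(apply_scenario(p, list())), unclass(p),
               ignore_attr = TRUE)
  q2 <- apply_scenario(q, list(mesh_incidence = 0.2))
  expect_equal(unclass(q2), unclass(q), ignore_attr = TRUE)

  expect_error(apply_scenario(p, list(nope = 1)), "mesh_incidence")
})
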