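#' Load a model parameter set from a configuration file
#'
#' Reads a YAML configuration whose sections mirror the fields of
#' [default_parameters()] (`strategies`, `effects`, `baseline_cure`,
#' `complications`, `retreatment`, `economics`, `utilities`, `costs`,
#' `uui_pathway`, `population`, `life_table`). The `life_table` entry is a
#' path, resolved relative to the configuration file, to a delimited text
#' file with header `age,qx`. Scalar keys missing inside a section are
#' filled from the shipped defaults and recorded as such in the provenance
#' attribute; missing sections are an error.
#'
#' @param path Path to the YAML configuration file.
#' @return A validated `sui_parameters` object with a `provenance`
#'   attribute (`"user"` for fields read from the file, the default
#'   provenance otherwise).
#' @seealso [write_parameters()] for the inverse, [validate_parameters()].
#' @export
#' @examples
#' cfg <- system.file("extdata", "default_config.yaml", package = "suicea")
#' p <- load_parameters(cfg)
#' p$effects[p$effects$strategy == "transob-MUS", ]
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  required <- c(
    "strategies", "effects", "baseline_cure", "complications",
    "retreatment", "economics", "utilities", "costs", "uui_pathway",
    "population", "life_table"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(
      "configuration is missing required section(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }

  as_tbl <- function(x, int_cols = character(), lgl_cols = character()) {
    tb <- dplyr::bind_rows(lapply(x, tibble::as_tibble))
    for (cc in intersect(int_cols, names(tb))) tb[[cc]] <- as.integer(tb[[cc]])
    for (cc in intersect(lgl_cols, names(tb))) tb[[cc]] <- as.logical(tb[[cc]])
    tb
  }

  lt_path <- raw$life_table
  if (!file.exists(lt_path)) {
    lt_path <- file.path(dirname(path), raw$life_table)
  }
  if (!file.exists(lt_path)) {
    stop("life_table file not found: ", raw$life_table, call. = FALSE)
  }
  lt <- tibble::as_tibble(read.csv(lt_path))
  if (!identical(names(lt), c("age", "qx"))) {
    stop("life_table must have header 'age,qx'", call. = FALSE)
  }
  lt$age <- as.integer(lt$age)

  def <- default_parameters()
  fill <- function(section, defaults) {
    extras <- setdiff(names(section), names(defaults))
    if (length(extras) > 0) {
      stop("unknown key(s) in configuration: ",
           paste(extras, collapse = ", "), call. = FALSE)
    }
    modifyList(defaults, section)
  }

  p <- structure(
    list(
      strategies = as_tbl(raw$strategies, lgl_cols = "reference"),
      effects = as_tbl(raw$effects),
      baseline_cure = as_tbl(raw$baseline_cure, int_cols = "time_months"),
      complications = as_tbl(raw$complications,
        int_cols = "duration_cycles", lgl_cols = "triggers_uui"
      ),
      retreatment = fill(raw$retreatment, def$retreatment),
      economics = fill(raw$economics, def$economics),
      utilities = as_tbl(raw$utilities),
      costs = list(
        procedure = as_tbl(raw$costs$procedure),
        followup_per_surgery = raw$costs$followup_per_surgery %||%
          def$costs$followup_per_surgery,
        containment_per_cycle = raw$costs$containment_per_cycle %||%
          def$costs$containment_per_cycle,
        cost_cv = raw$costs$cost_cv %||% def$costs$cost_cv
      ),
      uui_pathway = as_tbl(raw$uui_pathway, int_cols = c("line", "duration_cycles")),
      life_table = lt,
      population = fill(raw$population, def$population)
    ),
    class = "sui_parameters"
  )
  p$economics$wtp_grid <- as.numeric(p$economics$wtp_grid)
  p$economics$horizons <- as.character(p$economics$horizons)
  p$retreatment$max_surgeries <- as.integer(p$retreatment$max_surgeries)
  p$population$start_age <- as.integer(p$population$start_age)

  numeric_violations <- validate_structure(p)
  if (length(numeric_violations) > 0) {
    stop(
      "invalid value(s) in configuration: ",
      paste(numeric_violations, collapse = "; "),
      call. = FALSE
    )
  }

  prov <- attr(default_parameters(), "provenance")
  prov$provenance[prov$field %in% names(raw)] <- "user"
  attr(p, "provenance") <- prov
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hard structural checks applied at load time (types, parseability);
# scientific invariants live in validate_parameters()
validate_structure <- function(p) {
  out <- character()
  chk_num <- function(x, what) {
    if (!is.numeric(x) || anyNA(x)) out[[length(out) + 1]] <<- paste0(what, " must be numeric")
  }
  chk_num(p$effects$or_median, "effects$or_median")
  chk_num(p$baseline_cure$cure_prop, "baseline_cure$cure_prop")
  chk_num(p$complications$incidence, "complications$incidence")
  chk_num(p$utilities$value, "utilities$value")
  chk_num(p$costs$procedure$cost, "costs$procedure$cost")
  chk_num(p$life_table$qx, "life_table$qx")
  out
}

#' Serialise a parameter set to a configuration file
#'
#' Writes the YAML configuration and the companion `age,qx` life-table file
#' so that [load_parameters()] reproduces the object field-for-field.
#'
#' @param p A `sui_parameters` object.
#' @param path Output path for the YAML file.
#' @param life_table_path Output path for the life-table CSV; defaults to
#'   `life_table.csv` next to `path`. The YAML stores it as a relative path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path,
                             life_table_path = file.path(dirname(path), "life_table.csv")) {
  stopifnot(inherits(p, "sui_parameters"))
  write.csv(as.data.frame(p$life_table), life_table_path, row.names = FALSE,
            quote = FALSE)
  rowlist <- function(tb) lapply(seq_len(nrow(tb)), function(i) as.list(tb[i, ]))
  cfg <- list(
    strategies = rowlist(p$strategies),
    effects = rowlist(p$effects),
    baseline_cure = rowlist(p$baseline_cure),
    complications = rowlist(p$complications),
    retreatment = p$retreatment,
    economics = p$economics,
    utilities = rowlist(p$utilities),
    costs = list(
      procedure = rowlist(p$costs$procedure),
      followup_per_surgery = p$costs$followup_per_surgery,
      containment_per_cycle = p$costs$containment_per_cycle,
      cost_cv = p$costs$cost_cv
    ),
    uui_pathway = rowlist(p$uui_pathway),
    population = p$population,
    life_table = basename(life_table_path)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Validate a parameter set against the model's invariants
#'
#' Checks every structural and scientific invariant the model relies on:
#' the nine canonical strategies with their settings and a unique
#' retro-MUS reference; credible-interval ordering of the cure odds ratios;
#' presence of the 12- and 60-month baseline cure anchors; probability,
#' utility and cost ranges; the re-treatment mix summing to one and the
#' three-surgery cap; a contiguous life table starting below age 45; and a
#' willingness-to-pay grid containing the 20,000 and 30,000 thresholds.
#'
#' Violations are returned, not raised, so callers can report them all at
#' once.
#'
#' @param p A `sui_parameters` object.
#' @return A tibble with columns `field`, `rule` and `message`; zero rows
#'   if and only if the set is valid.
#' @export
#' @examples
#' validate_parameters(default_parameters())
validate_parameters <- function(p) {
  v <- list()
  add <- function(field, rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      field = field, rule = rule, message = message
    )
  }
  canon <- sui_strategies()

  s <- p$strategies
  if (nrow(s) != 9 || anyDuplicated(s$id) > 0 ||
      !setequal(s$id, canon$id)) {
    add("strategies", "nine-distinct",
        "exactly the nine canonical strategies are required")
  } else {
    m <- merge(s, canon, by = "id", suffixes = c("", ".canon"))
    if (any(m$setting != m$setting.canon)) {
      add("strategies", "setting",
          "treatment setting must match the canonical day-case/inpatient assignment")
    }
    if (sum(s$reference) != 1 || s$id[s$reference][1] != "retro-MUS") {
      add("strategies", "reference", "retro-MUS must be the unique reference")
    }
  }

  e <- p$effects
  if ("retro-MUS" %in% e$strategy) {
    add("effects", "no-reference-effect",
        "the reference strategy has an implicit OR of 1 and no effect row")
  }
  if (!setequal(e$strategy, setdiff(canon$id, "retro-MUS"))) {
    add("effects", "coverage",
        "one effect estimate per non-reference strategy is required")
  }
  if (any(e$or_median <= 0 | e$crl_low <= 0 | e$crl_high <= 0)) {
    add("effects", "positive", "odds ratios and bounds must be positive")
  }
  if (any(e$crl_low > e$or_median | e$or_median > e$crl_high)) {
    add("effects", "interval-order",
        "credible bounds must bracket the median (crl_low <= or_median <= crl_high)")
  }

  b <- p$baseline_cure
  if (!all(c(12L, 60L) %in% b$time_months)) {
    add("baseline_cure", "anchors",
        "12- and 60-month cure entries are required for the recurrence fit")
  }
  if (any(b$cure_prop < 0 | b$cure_prop > 1 |
          b$crl_low < 0 | b$crl_high > 1)) {
    add("baseline_cure", "range", "cure proportions must lie in [0,1]")
  }
  if (any(b$crl_low > b$cure_prop | b$cure_prop > b$crl_high)) {
    add("baseline_cure", "interval-order",
        "credible bounds must bracket the cure proportion")
  }

  u <- p$utilities
  uval <- setNames(u$value, u$name)
  if (any(u$value < 0 | u$value > 1)) {
    add("utilities", "range", "utilities must lie in [0,1]")
  }
  if (!all(c("u_pre_treatment_sui", "u_cured", "u_containment", "u_uui") %in% u$name)) {
    add("utilities", "coverage", "all four health-state utilities are required")
  } else if (uval[["u_cured"]] < uval[["u_pre_treatment_sui"]]) {
    add("utilities", "order", "u_cured must be at least u_pre_treatment_sui")
  }

  cm <- p$complications
  if (any(cm$incidence < 0 | cm$incidence > 1)) {
    add("complications", "incidence-range", "incidences must lie in [0,1]")
  }
  if (any(cm$utility_decrement < 0 | cm$utility_decrement > 1)) {
    add("complications", "decrement-range", "utility decrements must lie in [0,1]")
  }
  if ("u_pre_treatment_sui" %in% u$name &&
      any(cm$utility_decrement <= 1 &
            cm$utility_decrement > uval[["u_pre_treatment_sui"]] + 1e-12)) {
    add("complications", "decrement-baseline",
        "utility decrements may not exceed the pre-treatment baseline utility")
  }
  if (any(!is.finite(cm$duration_cycles)) || any(cm$duration_cycles < 0)) {
    add("complications", "duration", "durations must be finite and non-negative")
  }
  if (any(cm$one_off_cost < 0)) {
    add("complications", "cost", "complication costs must be non-negative")
  }
  if (any(cm$ess <= 0, na.rm = TRUE)) {
    add("complications", "ess", "beta effective sample sizes must be positive")
  }
  if (!all(cm$strategy %in% canon$id)) {
    add("complications", "strategy", "unknown strategy in complication table")
  }

  rt <- p$retreatment
  if (abs(rt$retreat_mix_retro + rt$retreat_mix_transob - 1) > 1e-9) {
    add("retreatment", "mix-sum",
        "retreat_mix_retro + retreat_mix_transob must equal 1")
  }
  for (nm in c("p_seek_first_retreat", "p_seek_second_retreat",
               "retreat_mix_retro", "retreat_mix_transob")) {
    if (rt[[nm]] < 0 || rt[[nm]] > 1) {
      add("retreatment", nm, paste0(nm, " must lie in [0,1]"))
    }
  }
  if (rt$retreat_effect_multiplier <= 0 || rt$retreat_effect_multiplier > 1) {
    add("retreatment", "multiplier",
        "retreat_effect_multiplier must lie in (0,1]")
  }
  if (rt$max_surgeries != 3L) {
    add("retreatment", "max-surgeries", "max_surgeries must equal 3")
  }

  ec <- p$economics
  if (ec$discount_rate_annual < 0) {
    add("economics", "discount", "discount rate must be non-negative")
  }
  if (any(ec$wtp_grid < 0)) {
    add("economics", "wtp-positive", "willingness-to-pay values must be non-negative")
  }
  if (!all(c(20000, 30000) %in% ec$wtp_grid)) {
    add("economics", "wtp-thresholds",
        "wtp grid must include the 20,000 and 30,000 thresholds")
  }
  if (!all(ec$horizons %in% c("1y", "10y", "lifetime"))) {
    add("economics", "horizons", "horizons must be among {1y, 10y, lifetime}")
  }

  co <- p$costs
  if (!setequal(co$procedure$strategy, canon$id)) {
    add("costs", "procedure-coverage", "a procedure cost per strategy is required")
  }
  if (any(co$procedure$cost < 0) || co$followup_per_surgery < 0 ||
      co$containment_per_cycle < 0) {
    add("costs", "non-negative", "costs must be non-negative")
  }

  uu <- p$uui_pathway
  if (!identical(sort(uu$line), 1:3)) {
    add("uui_pathway", "lines", "exactly treatment lines 1, 2, 3 are required")
  }
  if (any(uu$success_prob < 0 | uu$success_prob > 1)) {
    add("uui_pathway", "success-range", "line success probabilities must lie in [0,1]")
  }
  if (any(uu$duration_cycles < 1) || any(uu$cost < 0)) {
    add("uui_pathway", "duration-cost",
        "line durations must be >= 1 cycle and costs non-negative")
  }

  lt <- p$life_table
  if (min(lt$age) >= 45) {
    add("life_table", "start", "life table must start below age 45")
  }
  if (!identical(lt$age, seq(min(lt$age), max(lt$age)))) {
    add("life_table", "contiguous", "life-table ages must be contiguous integers")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    add("life_table", "qx-range", "annual death probabilities must lie in [0,1]")
  }

  pop <- p$population
  if (pop$start_age < min(lt$age) || pop$start_age > max(lt$age)) {
    add("population", "start-age", "start_age must lie within the life table")
  }
  if (pop$annual_affected <= 0) {
    add("population", "annual-affected", "annual_affected must be positive")
  }
  if (pop$p_uui_baseline < 0 || pop$p_uui_baseline > 1) {
    add("population", "uui-baseline", "p_uui_baseline must lie in [0,1]")
  }

  if (length(v) == 0) {
    tibble::tibble(field = character(), rule = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Apply a named sensitivity scenario to a parameter set
#'
#' Returns a modified copy of `p`; the input is never changed. Supported
#' scenario keys mirror the deterministic sensitivity analyses:
#'
#' * `mesh_incidence` — sets the mesh-removal complication incidence after
#'   both mid-urethral sling procedures (e.g. `0.10` or `0.20`).
#' * `persistent_pain_duration_years` — sets the persistent-pain duration
#'   (e.g. `3` or `5` years, converted to monthly cycles).
#' * `persistent_pain_incidence` — sets the persistent-pain incidence after
#'   both mid-urethral sling procedures (e.g. `0.10` or `0.20`).
#' * `cure_12m`, `cure_60m` — alternative short- and long-term reference
#'   cure proportions feeding the Weibull recurrence fit.
#'
#' @param p A `sui_parameters` object.
#' @param scenario Named list of scenario overrides; an empty list returns
#'   `p` unchanged.
#' @return A modified `sui_parameters` object; applied overrides are logged
#'   in the `scenario` attribute.
#' @export
#' @examples
#' p2 <- apply_scenario(default_parameters(), list(mesh_incidence = 0.2))
#' subset(p2$complications, name == "mesh-removal")
apply_scenario <- function(p, scenario = list()) {
  stopifnot(inherits(p, "sui_parameters"))
  supported <- c(
    "mesh_incidence", "persistent_pain_duration_years",
    "persistent_pain_incidence", "cure_12m", "cure_60m"
  )
  unknown <- setdiff(names(scenario), supported)
  if (length(unknown) > 0) {
    stop(
      "unknown scenario key(s): ", paste(unknown, collapse = ", "),
      "; supported keys are: ", paste(supported, collapse = ", "),
      call. = FALSE
    )
  }
  mus <- c("retro-MUS", "transob-MUS")
  q <- p
  for (key in names(scenario)) {
    val <- scenario[[key]]
    q <- switch(key,
      mesh_incidence = {
        i <- q$complications$name == "mesh-removal" &
          q$complications$strategy %in% mus
        q$complications$incidence[i] <- val
        q
      },
      persistent_pain_duration_years = {
        i <- q$complications$name == "persistent-pain"
        q$complications$duration_cycles[i] <- as.integer(round(val * 12))
        q
      },
      persistent_pain_incidence = {
        i <- q$complications$name == "persistent-pain" &
          q$complications$strategy %in% mus
        q$complications$incidence[i] <- val
        q
      },
      cure_12m = {
        q$baseline_cure$cure_prop[q$baseline_cure$time_months == 12L] <- val
        q
      },
      cure_60m = {
        q$baseline_cure$cure_prop[q$baseline_cure$time_months == 60L] <- val
        q
      }
    )
  }
  attr(q, "scenario") <- c(attr(p, "scenario"), scenario)
  q
}

#' @export
print.sui_parameters <- function(x, ...) {
  cat("<sui_parameters>\n")
  cat("  strategies:   ", nrow(x$strategies), " (reference: ",
      x$strategies$id[x$strategies$reference][1], ")\n", sep = "")
  cat("  effects:      ", nrow(x$effects), " odds ratios vs reference\n", sep = "")
  cat("  complications:", length(unique(x$complications$name)), "types\n")
  cat("  discount rate:", x$economics$discount_rate_annual, "\n")
  cat("  start age:    ", x$population$start_age, "\n", sep = "")
  sc <- attr(x, "scenario")
  if (!is.null(sc) && length(sc) > 0) {
    cat("  scenario:     ",
        paste(names(sc), unlist(sc), sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
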