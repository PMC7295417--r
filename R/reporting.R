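# pipeline entry points: deterministic, manifest-stamped runs that write
# publication-style delimited-text tables

run_manifest <- function(command, config, seed, extra = list()) {
  c(
    list(
      command = command,
      config = if (is.character(config)) config else "(in-memory parameters)",
      seed = seed,
      package_version = as.character(utils::packageVersion("suicea")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    extra
  )
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_params <- function(config) {
  if (inherits(config, "sui_parameters")) {
    return(config)
  }
  p <- load_parameters(config)
  v <- validate_parameters(p)
  if (nrow(v) > 0) {
    stop(
      "invalid configuration:\n",
      paste(sprintf("  [%s/%s] %s", v$field, v$rule, v$message),
            collapse = "\n"),
      call. = FALSE
    )
  }
  p
}

#' Run the deterministic base-case analysis
#'
#' Simulates every strategy at the median parameter values, then writes a
#' cohort-results table and an incremental cost-effectiveness table per
#' horizon, plus a JSON manifest recording the invocation, to `out_dir`.
#' Repeated invocations with the same inputs produce identical outputs.
#'
#' @param config Path to a YAML configuration, or a `sui_parameters`
#'   object.
#' @param horizons Character vector among `"1y"`, `"10y"`, `"lifetime"`.
#' @param n_patients Women simulated per strategy.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param scenario Optional named list passed to [apply_scenario()].
#' @return A named list of `sui_icer` tables, one per horizon, invisibly
#'   returned with the cohort tibbles as the `cohorts` attribute.
#' @export
run_basecase <- function(config, horizons = "lifetime", n_patients = 2000,
                         seed = 1, out_dir = NULL, scenario = NULL) {
  p <- resolve_params(config)
  scenario_name <- "none"
  if (!is.null(scenario) && length(scenario) > 0) {
    p <- apply_scenario(p, scenario)
    scenario_name <- paste(names(scenario), unlist(scenario),
                           sep = "=", collapse = ",")
  }
  bad <- setdiff(horizons, c("1y", "10y", "lifetime"))
  if (length(bad) > 0) {
    stop("unknown horizon(s): ", paste(bad, collapse = ", "),
         "; must be among {1y, 10y, lifetime}", call. = FALSE)
  }
  icers <- list()
  cohorts <- list()
  for (h in horizons) {
    ctx <- compile_model(p, h)
    res <- dplyr::bind_rows(lapply(
      p$strategies$id,
      function(s) simulate_cohort(ctx, s, n = n_patients, seed = seed)
    ))
    cohorts[[h]] <- res
    icers[[h]] <- compute_icers(res)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(as.data.frame(res),
                file.path(out_dir, paste0("cohort_results_", h, ".csv")),
                row.names = FALSE, quote = FALSE)
      write_icer_table(icers[[h]],
                       file.path(out_dir, paste0("icer_table_", h, ".csv")))
    }
  }
  if (!is.null(out_dir)) {
    write_manifest(
      run_manifest("basecase", config, seed, list(
        horizons = horizons, n_patients = n_patients,
        scenario = scenario_name
      )),
      file.path(out_dir, "manifest_basecase.json")
    )
  }
  attr(icers, "cohorts") <- cohorts
  invisible(icers)
}

#' Run the probabilistic analysis with acceptability curves and value of
#' information
#'
#' Runs [run_psa()], then writes the draw-level sample, the
#' cost-effectiveness acceptability curves over the willingness-to-pay
#' grid, and a value-of-information table (per-person EVPI at each
#' threshold; population EVPI over 1, 5, 10, 15 and 20 years; EVPPI per
#' recorded parameter group at `wtp_voi`), plus a manifest.
#'
#' @inheritParams run_basecase
#' @param n_draws Parameter draws.
#' @param n_patients Women per draw and strategy.
#' @param horizon Single horizon for the probabilistic analysis.
#' @param wtp_grid Willingness-to-pay grid; defaults to the grid in the
#'   configuration.
#' @param wtp_voi Threshold at which the value-of-information quantities
#'   are evaluated (default 20,000).
#' @return The `sui_psa` sample, invisibly, with `ceac` and `voi`
#'   attributes.
#' @export
run_psa_analysis <- function(config, n_draws = 200, n_patients = 2000,
                             horizon = "lifetime", seed = 1,
                             wtp_grid = NULL, wtp_voi = 20000,
                             out_dir = NULL, scenario = NULL) {
  p <- resolve_params(config)
  scenario_name <- "none"
  if (!is.null(scenario) && length(scenario) > 0) {
    p <- apply_scenario(p, scenario)
    scenario_name <- paste(names(scenario), unlist(scenario),
                           sep = "=", collapse = ",")
  }
  if (is.null(wtp_grid)) wtp_grid <- p$economics$wtp_grid
  sample <- run_psa(p, n_draws = n_draws, n_patients_per_draw = n_patients,
                    horizon = horizon, seed = seed)
  curves <- ceac(sample, wtp_grid)
  pp <- vapply(wtp_grid, function(w) evpi_per_person(sample, w), numeric(1))
  evpi_tab <- tibble::tibble(
    wtp = wtp_grid,
    evpi_per_person = pp,
    evpi_per_person_qaly = ifelse(wtp_grid > 0, pp / wtp_grid, NA_real_)
  )
  pp_voi <- evpi_per_person(sample, wtp_voi)
  pop_tab <- tibble::tibble(
    years = c(1L, 5L, 10L, 15L, 20L),
    population_evpi = vapply(
      c(1, 5, 10, 15, 20),
      function(y) population_evpi(pp_voi, p$population$annual_affected, y),
      numeric(1)
    )
  )
  groups <- attr(sample, "groups")
  evppi_tab <- tibble::tibble(
    parameter_group = names(groups),
    evppi = vapply(names(groups), function(g) evppi(sample, g, wtp_voi),
                   numeric(1)),
    wtp = wtp_voi
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psa(sample, out_dir)
    write_wtp_table(curves, file.path(out_dir, "ceac.csv"))
    write_wtp_table(evpi_tab, file.path(out_dir, "evpi_per_person.csv"))
    write.csv(as.data.frame(pop_tab),
              file.path(out_dir, "population_evpi.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(evppi_tab), file.path(out_dir, "evppi.csv"),
              row.names = FALSE, quote = FALSE)
    write_manifest(
      run_manifest("psa", config, seed, list(
        horizon = horizon, n_draws = n_draws, n_patients = n_patients,
        wtp_voi = wtp_voi, scenario = scenario_name
      )),
      file.path(out_dir, "manifest_psa.json")
    )
  }
  attr(sample, "ceac") <- curves
  attr(sample, "voi") <- list(evpi = evpi_tab, population = pop_tab,
                              evppi = evppi_tab)
  invisible(sample)
}

#' Run a named deterministic sensitivity scenario end to end
#'
#' Applies the scenario ([apply_scenario()]) and runs both the base case
#' and the probabilistic analysis, labelling every output with the
#' scenario.
#'
#' @inheritParams run_psa_analysis
#' @param scenario Named list of scenario overrides (see
#'   [apply_scenario()]).
#' @param horizons Horizons for the deterministic base case.
#' @return A list with elements `basecase` and `psa`.
#' @export
run_scenario <- function(config, scenario, horizons = "lifetime",
                         n_draws = 200, n_patients = 2000,
                         horizon = "lifetime", seed = 1, out_dir = NULL) {
  list(
    basecase = run_basecase(config, horizons = horizons,
                            n_patients = n_patients, seed = seed,
                            out_dir = out_dir, scenario = scenario),
    psa = run_psa_analysis(config, n_draws = n_draws,
                           n_patients = n_patients, horizon = horizon,
                           seed = seed, out_dir = out_dir,
                           scenario = scenario)
  )
}
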