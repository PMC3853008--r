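# CSV with a '#'-comment header carrying the config hash, so every output
# file is traceable to the exact configuration that produced it.
write_csv_stamped <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(format(df, trim = TRUE, digits = 10), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full projection pipeline from a configuration
#'
#' Calibrates the model, runs every configured scenario, and writes the
#' publication-style artifacts to the output directory:
#'
#' * `calibration_report.json` — solved rates, residuals, base-mortality
#'   schedule;
#' * `projection_<scenario>.csv` — tidy per-year, per-state projections;
#' * `table_projections.csv` — scenario-by-anchor-year summary;
#' * `table_comparison.csv` — prevented cases and relative attenuation;
#' * `table_sensitivity.csv` — one-variable-at-a-time analysis (when the
#'   `sensitivity` block is present);
#' * `run_log.txt` — versions, configuration hash and solver residuals.
#'
#' Every file carries the configuration hash; re-running an unchanged
#' configuration reproduces the outputs byte for byte.
#'
#' @param config A `run_config` (see [read_run_config()]) or a path to one.
#' @param output_dir Output directory (default from the config).
#' @return Invisibly, a list with the calibrated model, scenario results,
#'   summary tables and artifact paths.
#' @export
run_projection <- function(config = read_run_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  hash <- config_hash(config)
  if (is.null(output_dir)) {
    output_dir <- if (!is.null(config$output$directory)) {
      config$output$directory
    } else "glucostate_output"
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  ci <- config_to_inputs(config)
  model <- calibrate_model(inputs = ci$inputs, anchors = ci$anchors,
                           params = ci$params, births_per_year = ci$births,
                           migration_per_year = ci$migration,
                           end_year = ci$end_year)

  scen_names <- unique(c("none", unlist(config$scenarios)))
  results <- stats::setNames(
    lapply(scen_names, function(nm) run_scenario(model, nm)), scen_names)

  paths <- character(0)
  for (nm in scen_names) {
    p <- file.path(output_dir, paste0("projection_", nm, ".csv"))
    write_csv_stamped(as.data.frame(results[[nm]]), p, hash)
    paths <- c(paths, p)
  }
  p1 <- file.path(output_dir, "table_projections.csv")
  anchor_years <- intersect(ci$anchors$year, results$none$years)
  write_csv_stamped(scenario_table(results, years = anchor_years), p1, hash)
  p2 <- file.path(output_dir, "table_comparison.csv")
  comparison <- compare_scenarios(results)
  write_csv_stamped(comparison, p2, hash)
  paths <- c(paths, p1, p2)

  sens <- NULL
  if (!is.null(config$sensitivity)) {
    s <- config$sensitivity
    sens <- sensitivity_analysis(
      model,
      targeted_values = if (!is.null(s$targeted)) unlist(s$targeted) else c(0.0625, 0.25),
      population_values = if (!is.null(s$population)) unlist(s$population) else c(0.01, 0.04),
      increasing_background = isTRUE(s$increasing_background),
      background_rate_increase_pp =
        if (!is.null(s$background_rate_increase_pp)) s$background_rate_increase_pp else 3.5)
    p3 <- file.path(output_dir, "table_sensitivity.csv")
    write_csv_stamped(sens, p3, hash)
    paths <- c(paths, p3)
  }

  report <- list(
    config_hash = hash,
    solved_rates = model$params[c("detection_rate",
                                  "diagnosed_at_onset_fraction",
                                  "prog_normal_to_ifg", "prog_ifg_to_ifgigt")],
    residuals = model$residuals,
    iterations = model$iterations,
    base_death_rate = as.list(stats::setNames(model$demography$base_death_rate,
                                              model$demography$year))
  )
  pr <- file.path(output_dir, "calibration_report.json")
  jsonlite::write_json(report, pr, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  paths <- c(paths, pr)

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(c(
    paste0("glucostate ", as.character(utils::packageVersion("glucostate"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("config_hash: ", hash),
    paste0("calibration iterations: ", model$iterations),
    sprintf("diagnosed-share max deviation: %.6f",
            model$residuals$diagnosed_share_max_dev),
    sprintf("stratum-share max drift: %.6f",
            model$residuals$stratum_share_max_drift),
    sprintf("population-target max rel. deviation: %.3e",
            model$residuals$total_population_max_rel_dev),
    paste0("scenarios run: ", paste(scen_names, collapse = ", "))
  ), log_path)
  paths <- c(paths, log_path)

  invisible(list(model = model, results = results, comparison = comparison,
                 sensitivity = sens, paths = paths, config_hash = hash))
}

#' Run the emulator-based uncertainty pipeline from a configuration
#'
#' Requires the `emulator` block of the configuration.  For each configured
#' scenario family: runs the effectiveness design, fits the log-linear
#' emulator, propagates the subjective effectiveness distributions, and
#' writes `emulator_runs.csv`, `emulator_fits.json` and the credibility
#' interval table `table_uncertainty.csv`.
#'
#' @param config A `run_config` or path to one.
#' @param output_dir Output directory (default from the config).
#' @return Invisibly, a list with the uncertainty table, per-family fits,
#'   and artifact paths.
#' @export
run_uncertainty <- function(config = read_run_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (is.null(config$emulator)) {
    stop("configuration lacks the `emulator` block required for uncertainty analysis")
  }
  hash <- config_hash(config)
  if (is.null(output_dir)) {
    output_dir <- if (!is.null(config$output$directory)) {
      config$output$directory
    } else "glucostate_output"
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  ci <- config_to_inputs(config)
  model <- calibrate_model(inputs = ci$inputs, anchors = ci$anchors,
                           params = ci$params, births_per_year = ci$births,
                           migration_per_year = ci$migration,
                           end_year = ci$end_year)
  em <- config$emulator
  families <- if (!is.null(em$families)) unlist(em$families) else
    c("combined", "population", "high_risk", "moderate_risk")
  n_samples <- if (!is.null(em$n_samples)) em$n_samples else 10000
  seed <- if (!is.null(em$seed)) em$seed else 1L

  runs_all <- list(); fits <- list()
  for (fam in families) {
    runs <- design_runs(model, fam)
    fits[[fam]] <- fit_emulator(runs)
    runs$family <- fam
    runs_all[[fam]] <- as.data.frame(runs)
  }
  tab <- uncertainty_table(
    model, families = families,
    targeted_median = if (!is.null(em$targeted_median)) em$targeted_median else 0.125,
    population_median = if (!is.null(em$population_median)) em$population_median else 0.02,
    n_samples = n_samples, seed = seed)

  p1 <- file.path(output_dir, "emulator_runs.csv")
  write_csv_stamped(do.call(rbind, runs_all), p1, hash)
  p2 <- file.path(output_dir, "table_uncertainty.csv")
  write_csv_stamped(tab, p2, hash)
  p3 <- file.path(output_dir, "emulator_fits.json")
  jsonlite::write_json(list(
    config_hash = hash,
    fits = lapply(fits, function(f) f[c("family", "intercept", "coef_lnx1",
                                        "coef_lnx2", "r_squared",
                                        "residual_sd")])
  ), p3, auto_unbox = TRUE, digits = 12, pretty = TRUE)

  invisible(list(model = model, table = tab, fits = fits,
                 paths = c(p1, p2, p3), config_hash = hash))
}

#' Write the synthetic fixtures to a directory
#'
#' Regenerates the toy fixture and a default synthetic demography as plain
#' CSV files, for inspection or for use as worked examples.
#'
#' @param dir Output directory.
#' @param spec A [synthetic_spec()] for the demography fixture.
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir = "fixtures", spec = synthetic_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- generate_toy_fixture()
  p1 <- file.path(dir, "toy_initial_state.csv")
  utils::write.csv(data.frame(state = glucose_states(),
                              count_millions = unname(toy$initial$counts)),
                   p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, "toy_transition_matrix.csv")
  utils::write.csv(as.data.frame(toy$matrix$p), p2, quote = FALSE)
  p3 <- file.path(dir, "synthetic_demography.csv")
  utils::write.csv(as.data.frame(generate_demography(spec)), p3,
                   row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
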