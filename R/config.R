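#' Read and validate a run configuration
#'
#' Run configurations are YAML files grouping the model's tunable inputs:
#' epidemiologic parameters, calibration inputs (starting prevalences,
#' count/rate anchors, entrant flows), the scenario list, the projection
#' horizon, the sensitivity grid, and the emulator block.  `read_run_config()`
#' with no path loads the packaged default configuration, which encodes the
#' base case.  Configurations are validated against the known key schema
#' before any computation; unknown keys are rejected.
#'
#' @param path Path to a YAML configuration, or `NULL` for the packaged
#'   default.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "glucostate", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

config_schema <- function() {
  list(
    parameters = c("lambda_normal", "lambda_ifg", "lambda_ifgigt",
                   "overall_incidence", "rr_undiag", "rr_diag",
                   "incidence_growth"),
    calibration = c("total_dm_rate", "ifg_rate_any", "ifg_igt_rate",
                    "diagnosed_share_of_dm", "births_per_year",
                    "migration_per_year", "anchors"),
    scenarios = NULL,   # list of scenario names
    horizon = c("start_year", "end_year"),
    sensitivity = c("targeted", "population", "increasing_background",
                    "background_rate_increase_pp"),
    emulator = c("families", "n_samples", "seed",
                 "targeted_median", "population_median"),
    output = c("directory")
  )
}

#' Validate a run configuration list
#'
#' @param cfg Configuration list (as parsed from YAML).
#' @return The configuration, invisibly classed `run_config`; errors on any
#'   unknown key, missing required block, or invalid value.
#' @export
validate_run_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("calibration", "horizon", "scenarios")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("missing configuration block(s): ", paste(missing, collapse = ", "))
  }
  for (block in intersect(names(cfg), names(schema))) {
    allowed <- schema[[block]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in `%s` block: %s",
                   block, paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$calibration$anchors)) {
    a <- cfg$calibration$anchors
    if (!all(c("years", "counts", "rates") %in% names(a)) ||
        length(a$years) != length(a$counts) ||
        length(a$years) != length(a$rates)) {
      stop("`calibration$anchors` needs equal-length years/counts/rates")
    }
  }
  valid_scen <- c("none", "high_risk", "moderate_risk", "population", "combined")
  bad_scen <- setdiff(unlist(cfg$scenarios), valid_scen)
  if (length(bad_scen)) {
    stop("unknown scenario name(s): ", paste(bad_scen, collapse = ", "))
  }
  if (cfg$horizon$end_year <= cfg$horizon$start_year) {
    stop("`horizon$end_year` must exceed `horizon$start_year`")
  }
  structure(cfg, class = c("run_config", "list"))
}

# canonical md5 hash of a configuration (used to stamp every output file)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# assemble model inputs from a validated config
config_to_inputs <- function(cfg) {
  cal <- cfg$calibration
  anchors <- if (!is.null(cal$anchors)) {
    data.frame(year = cal$anchors$years, count = cal$anchors$counts,
               rate = cal$anchors$rates)
  } else default_anchors()
  pick <- function(block, name, default) {
    if (!is.null(block[[name]])) block[[name]] else default
  }
  params <- do.call(epi_parameters, c(
    cfg$parameters[intersect(names(cfg$parameters),
                             names(formals(epi_parameters)))]))
  inputs <- prevalence_inputs(
    year = cfg$horizon$start_year,
    total_dm_rate = pick(cal, "total_dm_rate", 0.129),
    ifg_rate_any = pick(cal, "ifg_rate_any", 0.267),
    ifg_igt_rate = pick(cal, "ifg_igt_rate", 0.083),
    diagnosed_share_of_dm = pick(cal, "diagnosed_share_of_dm", 0.718))
  list(params = params, inputs = inputs, anchors = anchors,
       births = pick(cal, "births_per_year", 4.2),
       migration = pick(cal, "migration_per_year", 1.0),
       end_year = cfg$horizon$end_year)
}
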