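#' One-variable-at-a-time sensitivity analysis
#'
#' Re-runs the four intervention strategies while varying one base-case
#' assumption at a time: the lifestyle-intervention effectiveness (half and
#' double its 12.5% base case), the population-wide effectiveness (half and
#' double 2%), and the background incidence trend (flat versus increasing,
#' the latter calibrated so the no-intervention horizon prevalence rate
#' rises by `background_rate_increase_pp` points over the flat scenario).
#' For every assumption row and strategy, reports the reduction in
#' horizon-year diabetes prevalence versus that row's own no-intervention
#' run, both in percentage points of prevalence rate and in millions of
#' prevalent cases.
#'
#' @param model A flat-trend `calibrated_model`.
#' @param targeted_values Alternative targeted effectiveness values (the
#'   base case must be among them or is added).
#' @param population_values Alternative population-wide effectiveness values.
#' @param targeted_base,population_base Base-case effectiveness values.
#' @param increasing_background Also evaluate the increasing-incidence
#'   background scenario?
#' @param background_rate_increase_pp Calibration target for the increasing
#'   background (percentage points above the flat-trend horizon rate).
#' @return Data frame in long format: `assumption`, `scenario`,
#'   `rate_reduction_pp`, `prevented_prevalent_millions`.
#' @export
sensitivity_analysis <- function(model,
                                 targeted_values = c(0.0625, 0.25),
                                 population_values = c(0.01, 0.04),
                                 targeted_base = 0.125,
                                 population_base = 0.02,
                                 increasing_background = TRUE,
                                 background_rate_increase_pp = 3.5) {
  stopifnot(inherits(model, "calibrated_model"))
  strategies <- c("moderate_risk", "high_risk", "population", "combined")

  eval_row <- function(m, label, t_eff, p_eff) {
    none <- run_scenario(m, "none")
    last <- length(none$years)
    do.call(rbind, lapply(strategies, function(s) {
      r <- run_scenario(m, make_scenario(s, targeted_eff = t_eff,
                                         population_eff = p_eff,
                                         start_year = m$initial$year))
      data.frame(
        assumption = label,
        scenario = s,
        rate_reduction_pp =
          100 * (none$prevalence_rate[last] - r$prevalence_rate[last]),
        prevented_prevalent_millions =
          none$prevalence_millions[last] - r$prevalence_millions[last],
        stringsAsFactors = FALSE
      )
    }))
  }

  rows <- list(eval_row(model, "base_case", targeted_base, population_base))
  if (increasing_background) {
    inc <- calibrate_incidence_growth(model, background_rate_increase_pp)
    rows <- c(rows, list(eval_row(inc, "increasing_background",
                                  targeted_base, population_base)))
  }
  for (tv in setdiff(targeted_values, targeted_base)) {
    rows <- c(rows, list(eval_row(model, sprintf("targeted_eff_%g", tv),
                                  tv, population_base)))
  }
  for (pv in setdiff(population_values, population_base)) {
    rows <- c(rows, list(eval_row(model, sprintf("population_eff_%g", pv),
                                  targeted_base, pv)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
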