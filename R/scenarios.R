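#' Prevention-policy scenarios
#'
#' Constructs one of the five hypothetical national diabetes prevention
#' strategies compared by the model:
#'
#' * `none` — no intervention; current trends continue unabated.
#' * `high_risk` — structured lifestyle intervention for adults with both
#'   IFG and IGT (targets `IFG_IGT` only).
#' * `moderate_risk` — structured lifestyle intervention for all adults with
#'   IFG regardless of IGT status (targets `IFG_ONLY` and `IFG_IGT`).
#' * `population` — population-wide risk-reduction policies lowering
#'   diabetes incidence in every non-diabetic state.
#' * `combined` — the moderate-risk and population strategies applied
#'   simultaneously; their incidence multipliers compose.
#'
#' Effectiveness is expressed as the net fractional reduction in the annual
#' diabetes incidence rate of the targeted states: by default 12.5% for the
#' lifestyle intervention (the rule-of-halves cascade, see
#' [net_effectiveness()]) and 2% for the population-wide policies.
#'
#' @param name One of `"none"`, `"high_risk"`, `"moderate_risk"`,
#'   `"population"`, `"combined"`.
#' @param targeted_eff Net incidence reduction in the lifestyle-targeted
#'   states (fraction in `[0, 1)`).
#' @param population_eff Net incidence reduction applied population-wide
#'   (fraction in `[0, 1)`).
#' @param start_year First transition year the intervention applies to.
#' @return An object of class `intervention_scenario`.
#' @export
make_scenario <- function(name = c("none", "high_risk", "moderate_risk",
                                   "population", "combined"),
                          targeted_eff = 0.125,
                          population_eff = 0.02,
                          start_year = 2007) {
  name <- match.arg(name)
  stopifnot(targeted_eff >= 0, targeted_eff < 1,
            population_eff >= 0, population_eff < 1)
  target_states <- switch(name,
    none = character(0),
    high_risk = "IFG_IGT",
    moderate_risk = c("IFG_ONLY", "IFG_IGT"),
    population = character(0),
    combined = c("IFG_ONLY", "IFG_IGT"))
  structure(list(
    name = name,
    target_states = target_states,
    targeted_effectiveness = if (name %in% c("none", "population")) 0 else targeted_eff,
    population_effectiveness = if (name %in% c("population", "combined")) population_eff else 0,
    start_year = as.integer(start_year)
  ), class = "intervention_scenario")
}

#' Per-state incidence multipliers implied by a scenario
#'
#' Returns the factor by which a scenario scales the annual diabetes
#' incidence probability out of each non-diabetic state: `(1 - targeted
#' effectiveness)` in the lifestyle-targeted states, composed with
#' `(1 - population-wide effectiveness)` everywhere when the population
#' strategy is active.
#'
#' @param scenario An `intervention_scenario`, or `NULL` for no intervention.
#' @return Named numeric vector over [nondm_states()].
#' @export
incidence_multipliers <- function(scenario = NULL) {
  m <- stats::setNames(rep(1, length(nondm_states())), nondm_states())
  if (is.null(scenario) || scenario$name == "none") return(m)
  unknown <- setdiff(scenario$target_states, glucose_states())
  if (length(unknown)) stop("scenario targets unknown state(s): ",
                            paste(unknown, collapse = ", "))
  m[scenario$target_states] <- m[scenario$target_states] *
    (1 - scenario$targeted_effectiveness)
  m <- m * (1 - scenario$population_effectiveness)
  m
}

#' @export
print.intervention_scenario <- function(x, ...) {
  cat("Intervention scenario:", x$name, "\n")
  if (length(x$target_states)) {
    cat(sprintf("  targeted states %s, effectiveness %.4f\n",
                paste(x$target_states, collapse = "+"),
                x$targeted_effectiveness))
  }
  if (x$population_effectiveness > 0) {
    cat(sprintf("  population-wide effectiveness %.4f\n",
                x$population_effectiveness))
  }
  cat("  applied from the", x$start_year, "transition onward\n")
  invisible(x)
}

#' Net effectiveness of an intervention cascade
#'
#' Net fractional incidence reduction achieved when only a fraction of the
#' target population is identified, only a fraction of those identified
#' participate, and participants experience a given relative incidence
#' reduction ("rule of halves": 0.5 x 0.5 x 0.5 = 12.5%).
#'
#' @param identified Fraction of the target population identified.
#' @param participates Fraction of those identified who participate.
#' @param efficacy Relative incidence reduction among participants.
#' @return The product of the three fractions.
#' @export
net_effectiveness <- function(identified, participates, efficacy) {
  args <- c(identified = identified, participates = participates,
            efficacy = efficacy)
  if (any(args < 0 | args > 1)) stop("all cascade fractions must lie in [0, 1]")
  identified * participates * efficacy
}

#' Relative attenuation of the projected increase in diabetes prevalence
#'
#' Compares the 2007-to-horizon change in diabetes prevalence (rate in
#' percentage points, or count in millions) between a baseline run and an
#' intervention run: `100 * (change_baseline - change_scenario) /
#' change_baseline`.
#'
#' @param baseline,scenario `projection_result` objects sharing start year
#'   and horizon.
#' @param measure `"rate"` (prevalence rate, the headline measure) or
#'   `"count"` (prevalent cases in millions).
#' @return Relative attenuation in percent.
#' @export
relative_attenuation <- function(baseline, scenario, measure = c("rate", "count")) {
  measure <- match.arg(measure)
  stopifnot(inherits(baseline, "projection_result"),
            inherits(scenario, "projection_result"))
  if (baseline$years[1] != scenario$years[1] ||
      utils::tail(baseline$years, 1) != utils::tail(scenario$years, 1)) {
    stop("baseline and scenario runs must share start year and horizon")
  }
  series <- function(r) {
    if (measure == "rate") 100 * r$prevalence_rate else r$prevalence_millions
  }
  delta <- function(r) {
    s <- series(r)
    s[length(s)] - s[1]
  }
  d0 <- delta(baseline)
  if (abs(d0) < .Machine$double.eps) stop("baseline change is zero; attenuation undefined")
  100 * (d0 - delta(scenario)) / d0
}

#' Summarize intervention scenarios against the no-intervention baseline
#'
#' For each scenario run, computes the quantities reported when comparing
#' prevention strategies: incident cases prevented through the horizon
#' (difference in cumulative incidence), prevalent cases prevented at the
#' horizon, the horizon prevalence rate, the 2007-to-horizon changes, and
#' the relative attenuation of those changes.
#'
#' @param results Named list of `projection_result` objects; must contain an
#'   element named `"none"`.
#' @return A data frame with one row per scenario.
#' @export
compare_scenarios <- function(results) {
  if (!"none" %in% names(results)) {
    stop("`results` must include the no-intervention run under the name \"none\"")
  }
  none <- results[["none"]]
  last <- length(none$years)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(
      scenario = nm,
      cumulative_incidence = r$cumulative_incidence[last],
      prevented_cumulative_cases =
        none$cumulative_incidence[last] - r$cumulative_incidence[last],
      prevalent_millions = r$prevalence_millions[last],
      prevented_prevalent_cases =
        none$prevalence_millions[last] - r$prevalence_millions[last],
      rate_pct = 100 * r$prevalence_rate[last],
      count_change = r$prevalence_millions[last] - r$prevalence_millions[1],
      rate_change_pp = 100 * (r$prevalence_rate[last] - r$prevalence_rate[1]),
      relative_attenuation_count = if (nm == "none") NA_real_ else
        relative_attenuation(none, r, "count"),
      relative_attenuation_rate = if (nm == "none") NA_real_ else
        relative_attenuation(none, r, "rate"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Projection summary table across scenarios and anchor years
#'
#' Long-format analogue of a projections table: cumulative incidence,
#' prevalent cases and prevalence rate for each scenario at the requested
#' years, plus the 2007-to-horizon change and relative attenuation.
#'
#' @param results Named list of `projection_result`s including `"none"`.
#' @param years Calendar years to tabulate (default the printed anchors).
#' @return A data frame in long format.
#' @export
scenario_table <- function(results,
                           years = c(2007, 2010, 2015, 2020, 2025, 2030)) {
  if (!"none" %in% names(results)) stop("`results` must include \"none\"")
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    idx <- match(years, r$years)
    if (anyNA(idx)) stop("requested years outside the projection horizon")
    data.frame(
      scenario = nm,
      year = years,
      cumulative_incidence_millions = r$cumulative_incidence[idx],
      prevalence_millions = r$prevalence_millions[idx],
      prevalence_rate_pct = 100 * r$prevalence_rate[idx],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
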