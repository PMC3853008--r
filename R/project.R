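#' Project the five-state population forward
#'
#' Runs the annual difference equation `N(t) = N(t-1) P(t) + B(t) + M(t)`
#' from the initial state to `end_year`, accumulating incident diabetes
#' cases, deaths, and prevalence.
#'
#' Timing convention: the state vector is recorded at the start of each
#' calendar year, and each transition is labelled by the year it starts in.
#' Incident cases "in year y" are the inflow into the diabetes states during
#' the transition `N(y) -> N(y+1)`; the cumulative incidence reported at
#' year `y` sums the transitions starting in the first projection year
#' through `y` inclusive.  The final year's incident cases are therefore
#' computed from one additional transition-matrix application whose state
#' advance is discarded.
#'
#' In a census-constrained schedule (see [demography_schedule()]) the base
#' death rate for each transition is solved in closed form so the next
#' year's total matches its target exactly:
#' `b(y) = (total(y) + B(y) + M(y) - target(y+1)) / sum_s N_s(y) rr_s`.
#' An error is raised if the implied rate leaves `[0, 0.1]`.
#'
#' @param initial A [state_vector()] at the first projection year.
#' @param params A fully resolved [epi_parameters()] object.
#' @param demography A [demography_schedule()] covering the horizon.
#' @param scenario An `intervention_scenario` or `NULL` (no intervention).
#' @param end_year Final calendar year of the projection.
#' @return An object of class `projection_result` with per-year state
#'   counts, totals, diabetes prevalence (millions and rate), per-year and
#'   cumulative incident cases, per-state deaths, and the base death rates
#'   used.
#' @export
project <- function(initial, params, demography, scenario = NULL,
                    end_year) {
  stopifnot(inherits(initial, "state_vector"),
            inherits(params, "epi_parameters"),
            inherits(demography, "demography_schedule"))
  if (end_year <= initial$year) stop("`end_year` must exceed the initial year")
  if (initial$year != demography$year[1]) {
    stop("initial state year must equal the first demography year")
  }
  years <- seq.int(initial$year, end_year)
  n <- length(years)
  rr <- c(1, 1, 1, params$rr_undiag, params$rr_diag)

  counts <- matrix(NA_real_, n, n_states(),
                   dimnames = list(years, glucose_states()))
  incidence <- deaths_total <- base_rates <- numeric(n)
  deaths <- matrix(NA_real_, n, n_states(),
                   dimnames = list(years, glucose_states()))

  state <- initial
  for (i in seq_len(n)) {
    y <- years[i]
    counts[i, ] <- state$counts
    row <- demography_row(demography, y)
    b <- row$base_death_rate
    if (is.na(b)) {
      if (i < n) {
        target_next <- demography_row(demography, y + 1L)$total
        b <- (sum(state$counts) + row$births + row$migration - target_next) /
          sum(state$counts * rr)
      } else {
        # final bookkeeping transition: reuse the last solved rate
        b <- base_rates[i - 1L]
      }
      if (b < 0 || b > 0.1) {
        stop(sprintf(
          "implied base death rate %.5f for year %d outside [0, 0.1]; demography infeasible",
          b, y))
      }
    }
    base_rates[i] <- b
    mat <- build_transition_matrix(params, b, scenario, year = y,
                                   start_year = years[1])
    p <- mat$p
    incidence[i] <- sum(state$counts[nondm_states()] *
                          (p[nondm_states(), "UNDIAG_DM"] +
                             p[nondm_states(), "DIAG_DM"]))
    deaths[i, ] <- state$counts * mat$death_rates
    deaths_total[i] <- sum(deaths[i, ])
    if (i < n) {
      births_vec <- c(row$births, 0, 0, 0, 0)
      mig_vec <- row$migration * state$counts / sum(state$counts)
      state <- step(state, mat, births_vec, mig_vec)
    }
  }

  total <- rowSums(counts)
  dm <- counts[, "UNDIAG_DM"] + counts[, "DIAG_DM"]
  structure(list(
    scenario = if (is.null(scenario)) "none" else scenario$name,
    years = years,
    counts = counts,
    total = total,
    prevalence_millions = dm,
    prevalence_rate = dm / total,
    incidence = incidence,
    cumulative_incidence = cumsum(incidence),
    deaths = deaths,
    deaths_total = deaths_total,
    base_death_rate = base_rates,
    params = params
  ), class = "projection_result")
}

#' Cumulative incident diabetes cases per year
#'
#' Running total of new diabetes cases (millions) since the first projection
#' year, one value per transition year; non-decreasing by construction.
#'
#' @param result A `projection_result`.
#' @return Named numeric vector (names are years).
#' @export
cumulative_incidence_series <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  stats::setNames(result$cumulative_incidence, result$years)
}

#' @export
print.projection_result <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("Projection %d-%d, scenario \"%s\"\n",
              x$years[1], x$years[n], x$scenario))
  cat(sprintf("  %d: %.1fM with diabetes (%.1f%% of %.1fM adults)\n",
              x$years[1], x$prevalence_millions[1],
              100 * x$prevalence_rate[1], x$total[1]))
  cat(sprintf("  %d: %.1fM with diabetes (%.1f%% of %.1fM adults)\n",
              x$years[n], x$prevalence_millions[n],
              100 * x$prevalence_rate[n], x$total[n]))
  cat(sprintf("  cumulative incidence through %d: %.1fM\n",
              x$years[n], x$cumulative_incidence[n]))
  invisible(x)
}

#' @export
as.data.frame.projection_result <- function(x, ...) {
  n <- length(x$years)
  data.frame(
    year = rep(x$years, times = n_states()),
    state = rep(glucose_states(), each = n),
    count_millions = as.vector(x$counts),
    prevalence_rate = rep(x$prevalence_rate, times = n_states()),
    cumulative_incidence_millions = rep(x$cumulative_incidence,
                                        times = n_states()),
    scenario = x$scenario,
    stringsAsFactors = FALSE
  )
}
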