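#' Starting prevalence inputs
#'
#' The 2007 starting prevalences among US adults (NHANES 2005-2008 summary
#' estimates): total diabetes (diagnosed plus undiagnosed) 12.9%, IFG
#' regardless of IGT status 26.7%, combined IFG and IGT 8.3%.  The split of
#' total diabetes into diagnosed and undiagnosed is not published for 2007;
#' it defaults to 0.718 diagnosed, the ratio implied by the projected 2030
#' diagnosed (16.3%) and total (22.7%) prevalence rates, which the model
#' holds roughly stable.
#'
#' @param year Anchor year of the prevalences.
#' @param total_dm_rate Prevalence of total diabetes (fraction).
#' @param ifg_rate_any Prevalence of IFG regardless of IGT status.
#' @param ifg_igt_rate Prevalence of combined IFG and IGT.
#' @param diagnosed_share_of_dm Diagnosed fraction of total diabetes.
#' @return An object of class `prevalence_inputs`.
#' @export
prevalence_inputs <- function(year = 2007,
                              total_dm_rate = 0.129,
                              ifg_rate_any = 0.267,
                              ifg_igt_rate = 0.083,
                              diagnosed_share_of_dm = 0.718) {
  stopifnot(ifg_igt_rate <= ifg_rate_any,
            total_dm_rate + ifg_rate_any < 1,
            total_dm_rate > 0, diagnosed_share_of_dm >= 0,
            diagnosed_share_of_dm <= 1)
  structure(list(year = as.integer(year),
                 total_dm_rate = total_dm_rate,
                 ifg_rate_any = ifg_rate_any,
                 ifg_igt_rate = ifg_igt_rate,
                 diagnosed_share_of_dm = diagnosed_share_of_dm),
            class = "prevalence_inputs")
}

#' Published projection anchors used as population targets
#'
#' No-intervention diabetes prevalence counts (millions) and rates at six
#' anchor years.  Dividing count by rate at each anchor back-derives the
#' census-consistent total adult population that the model is constrained
#' to follow.
#'
#' @return Data frame with columns `year`, `count`, `rate`.
#' @export
default_anchors <- function() {
  data.frame(
    year = c(2007, 2010, 2015, 2020, 2025, 2030),
    count = c(27.8, 33.1, 41.2, 48.7, 55.3, 60.7),
    rate = c(0.129, 0.148, 0.175, 0.197, 0.215, 0.227)
  )
}

#' Derive per-year total-population targets from count/rate anchors
#'
#' Each anchor's total is `count / rate`; intermediate years are filled by
#' geometric (constant-growth) interpolation between consecutive anchors.
#'
#' @param anchors Data frame with columns `year`, `count` (millions) and
#'   `rate` (fraction), at two or more anchor years.
#' @return Named numeric vector of totals (millions), one per year from the
#'   first to the last anchor year.
#' @export
derive_population_targets <- function(anchors = default_anchors()) {
  stopifnot(nrow(anchors) >= 2, all(diff(anchors$year) > 0))
  if (any(anchors$rate <= 0)) stop("prevalence rates must be strictly positive")
  totals_anchor <- anchors$count / anchors$rate
  years <- seq.int(anchors$year[1], anchors$year[nrow(anchors)])
  out <- stats::setNames(numeric(length(years)), years)
  for (k in seq_len(nrow(anchors) - 1)) {
    y0 <- anchors$year[k]; y1 <- anchors$year[k + 1]
    t0 <- totals_anchor[k]; t1 <- totals_anchor[k + 1]
    span <- y1 - y0
    for (y in y0:y1) {
      out[as.character(y)] <- t0 * (t1 / t0)^((y - y0) / span)
    }
  }
  out
}

#' Build the initial state vector from starting prevalences
#'
#' Allocates the total adult population across the five states:
#' `IFG_IGT = ifg_igt_rate`, `IFG_ONLY = ifg_rate_any - ifg_igt_rate`,
#' diabetes split by the diagnosed share, `NORMAL` the remainder.
#'
#' @param inputs A [prevalence_inputs()] object.
#' @param total_population Total adult population, millions.
#' @return A [state_vector()] whose counts sum to `total_population`.
#' @export
build_initial_state <- function(inputs, total_population) {
  stopifnot(inherits(inputs, "prevalence_inputs"), total_population > 0)
  shares <- c(
    NORMAL = 1 - inputs$total_dm_rate - inputs$ifg_rate_any,
    IFG_ONLY = inputs$ifg_rate_any - inputs$ifg_igt_rate,
    IFG_IGT = inputs$ifg_igt_rate,
    UNDIAG_DM = inputs$total_dm_rate * (1 - inputs$diagnosed_share_of_dm),
    DIAG_DM = inputs$total_dm_rate * inputs$diagnosed_share_of_dm
  )
  if (any(shares < 0)) stop("derived state shares are negative; check inputs")
  state_vector(inputs$year, shares * total_population)
}

#' Solve the per-year base death rate against population targets
#'
#' Closed-form inversion of the demographic identity: given a state
#' trajectory, entrant flows and total-population targets, the base death
#' rate of the non-diabetic states for the transition starting in year `y`
#' is `(total(y) + births(y) + migration(y) - target(y+1)) / sum_s N_s(y)
#' rr_s`, with the mortality relative risks applied to the diabetes states.
#'
#' @param demography A [demography_schedule()] with the targets and flows.
#' @param params An [epi_parameters()] object (for the relative risks).
#' @param result A `projection_result` supplying the state trajectory.
#' @return Numeric vector of base death rates per transition year (the last
#'   year repeats the previous rate, as no following target exists).
#' @export
solve_base_mortality <- function(demography, params, result) {
  stopifnot(inherits(result, "projection_result"))
  rr <- c(1, 1, 1, params$rr_undiag, params$rr_diag)
  years <- result$years
  n <- length(years)
  rates <- numeric(n)
  for (i in seq_len(n - 1)) {
    row <- demography_row(demography, years[i])
    target_next <- demography_row(demography, years[i] + 1L)$total
    N <- result$counts[i, ]
    rates[i] <- (sum(N) + row$births + row$migration - target_next) /
      sum(N * rr)
    if (rates[i] < 0 || rates[i] > 0.1) {
      stop(sprintf("implied base death rate %.5f in %d outside [0, 0.1]",
                   rates[i], years[i]))
    }
  }
  rates[n] <- rates[n - 1]
  stats::setNames(rates, years)
}

#' Solve detection and diagnosed-at-onset rates
#'
#' Chooses the annual detection probability (UNDIAG_DM to DIAG_DM) and the
#' fraction of incident diabetes diagnosed at onset so that, under baseline
#' no-intervention dynamics, the diagnosed share of total diabetes stays
#' close to `diagnosed_share_target` over the whole horizon.  Because both
#' rates are constant over time, the non-diabetes-to-diabetes transition
#' probabilities remain constant multiples of the detection rate.
#'
#' The two rates trade off along a near-stationary ridge, so the solver
#' minimizes the summed squared deviation of the diagnosed-share trajectory
#' from its target (L-BFGS-B from a fixed start; deterministic) and
#' requires the largest deviation to stay within `band`.
#'
#' @param params [epi_parameters()] with progression rates set.
#' @param initial Initial [state_vector()].
#' @param demography Census-constrained [demography_schedule()].
#' @param end_year Projection horizon.
#' @param diagnosed_share_target Target diagnosed fraction of total DM.
#' @param band Maximum tolerated absolute deviation of the share (0.02).
#' @return List with `detection_rate`, `diagnosed_at_onset_fraction` and
#'   `max_abs_deviation`.
#' @export
solve_detection_and_onset <- function(params, initial, demography, end_year,
                                      diagnosed_share_target = 0.718,
                                      band = 0.02) {
  stopifnot(diagnosed_share_target > 0, diagnosed_share_target < 1)
  share_dev <- function(par) {
    p <- update_parameters(params,
                           detection_rate = par[1],
                           diagnosed_at_onset_fraction = par[2])
    r <- project(initial, p, demography, scenario = NULL, end_year = end_year)
    share <- r$counts[, "DIAG_DM"] /
      (r$counts[, "DIAG_DM"] + r$counts[, "UNDIAG_DM"])
    share - diagnosed_share_target
  }
  obj <- function(par) sum(share_dev(par)^2)
  fit <- stats::optim(c(0.2, 0.5), obj, method = "L-BFGS-B",
                      lower = c(1e-6, 1e-6), upper = c(1, 1))
  dev <- share_dev(fit$par)
  if (max(abs(dev)) > band) {
    stop(sprintf(paste0("no (detection, onset) pair keeps the diagnosed share ",
                        "within %.3f of %.3f (best deviation %.4f)"),
                 band, diagnosed_share_target, max(abs(dev))))
  }
  list(detection_rate = fit$par[1],
       diagnosed_at_onset_fraction = fit$par[2],
       max_abs_deviation = max(abs(dev)))
}

#' Solve prediabetes progression rates for quasi-stationary strata
#'
#' Chooses the annual NORMAL-to-IFG and IFG-to-IFG+IGT progression
#' probabilities so that the IFG_ONLY and IFG_IGT shares of the
#' *non-diabetic* population drift as little as possible over the horizon
#' under no intervention (quasi-stationarity of the risk strata).  The
#' solver minimizes summed squared relative drift from the initial shares
#' and requires the relative drift to stay under `max_drift`.
#'
#' @param params [epi_parameters()] with detection/onset rates set.
#' @param initial Initial [state_vector()].
#' @param demography Census-constrained [demography_schedule()].
#' @param end_year Projection horizon.
#' @param max_drift Maximum tolerated relative drift of either share (0.10).
#' @return List with `prog_normal_to_ifg`, `prog_ifg_to_ifgigt` and
#'   `max_relative_drift`.
#' @export
solve_progression_rates <- function(params, initial, demography, end_year,
                                    max_drift = 0.10) {
  share0 <- initial$counts[c("IFG_ONLY", "IFG_IGT")] /
    sum(initial$counts[nondm_states()])
  rel_drift <- function(par) {
    p <- update_parameters(params,
                           prog_normal_to_ifg = par[1],
                           prog_ifg_to_ifgigt = par[2])
    r <- project(initial, p, demography, scenario = NULL, end_year = end_year)
    nondm <- rowSums(r$counts[, nondm_states()])
    cbind(r$counts[, "IFG_ONLY"] / nondm / share0[1] - 1,
          r$counts[, "IFG_IGT"] / nondm / share0[2] - 1)
  }
  obj <- function(par) sum(rel_drift(par)^2)
  fit <- stats::optim(c(0.02, 0.05), obj, method = "L-BFGS-B",
                      lower = c(1e-6, 1e-6), upper = c(1, 1))
  drift <- rel_drift(fit$par)
  if (max(abs(drift)) > max_drift) {
    stop(sprintf("risk-stratum shares drift by %.3f > %.3f; system infeasible",
                 max(abs(drift)), max_drift))
  }
  list(prog_normal_to_ifg = fit$par[1],
       prog_ifg_to_ifgigt = fit$par[2],
       max_relative_drift = max(abs(drift)))
}

#' Calibrate the projection model to in-paper anchors
#'
#' Derives everything the published summary quantities leave implicit so
#' that the no-intervention baseline satisfies the model's constraints:
#'
#' 1. total-population targets back-derived from the prevalence count/rate
#'    anchors (geometric interpolation between anchors);
#' 2. the initial state vector from the starting prevalences;
#' 3. detection / diagnosed-at-onset rates holding the diagnosed share of
#'    diabetes near its target;
#' 4. prediabetes progression rates holding the risk-stratum mix
#'    quasi-stationary;
#' 5. a per-year base death rate solved in closed form so the baseline run
#'    reproduces the population targets exactly, given exogenous entrant
#'    flows (births into NORMAL, migration allocated proportionally).
#'
#' Steps 3-4 are weakly coupled and iterated to a joint fixed point.  The
#' returned object carries the completed parameter set, the demography with
#' solved base rates (shared by intervention runs, whose totals then float
#' with their death counts), the baseline run and calibration residuals.
#'
#' @param inputs Starting [prevalence_inputs()].
#' @param anchors Count/rate anchor table (see [default_anchors()]).
#' @param params [epi_parameters()] supplying incidence and mortality RRs.
#' @param births_per_year New adults entering the population annually,
#'   millions (default 4.2, the approximate number of US residents turning
#'   20 each year over the horizon).
#' @param migration_per_year Net migration, millions/yr (default 1.0).
#' @param end_year Projection horizon (default 2030).
#' @param max_iter,tol Fixed-point iteration controls on the solved rates.
#' @return An object of class `calibrated_model`.
#' @export
calibrate_model <- function(inputs = prevalence_inputs(),
                            anchors = default_anchors(),
                            params = epi_parameters(),
                            births_per_year = 4.2,
                            migration_per_year = 1.0,
                            end_year = 2030,
                            max_iter = 100, tol = 1e-6) {
  targets <- derive_population_targets(anchors)
  years <- as.integer(names(targets))
  if (utils::tail(years, 1) < end_year) {
    stop("anchors do not cover the projection horizon")
  }
  demography <- demography_schedule(years, targets,
                                    births = births_per_year,
                                    migration = migration_per_year)
  initial <- build_initial_state(inputs, targets[[1]])

  # fixed-point iteration over the two weakly coupled rate solvers
  p <- update_parameters(params,
                         detection_rate = 0.2,
                         diagnosed_at_onset_fraction = 0.5,
                         prog_normal_to_ifg = 0.02,
                         prog_ifg_to_ifgigt = 0.05)
  det <- prog <- NULL
  for (it in seq_len(max_iter)) {
    old <- unlist(p[c("detection_rate", "diagnosed_at_onset_fraction",
                      "prog_normal_to_ifg", "prog_ifg_to_ifgigt")])
    det <- solve_detection_and_onset(p, initial, demography, end_year,
                                     inputs$diagnosed_share_of_dm)
    p <- update_parameters(p,
                           detection_rate = det$detection_rate,
                           diagnosed_at_onset_fraction = det$diagnosed_at_onset_fraction)
    prog <- solve_progression_rates(p, initial, demography, end_year)
    p <- update_parameters(p,
                           prog_normal_to_ifg = prog$prog_normal_to_ifg,
                           prog_ifg_to_ifgigt = prog$prog_ifg_to_ifgigt)
    new <- unlist(p[c("detection_rate", "diagnosed_at_onset_fraction",
                      "prog_normal_to_ifg", "prog_ifg_to_ifgigt")])
    if (max(abs(new - old)) < tol) break
  }

  baseline <- project(initial, p, demography, scenario = NULL,
                      end_year = end_year)
  demography$base_death_rate <- baseline$base_death_rate

  nondm0 <- sum(initial$counts[nondm_states()])
  structure(list(
    params = p,
    inputs = inputs,
    anchors = anchors,
    demography = demography,
    initial = initial,
    baseline = baseline,
    end_year = as.integer(end_year),
    residuals = list(
      diagnosed_share_max_dev = det$max_abs_deviation,
      stratum_share_max_drift = prog$max_relative_drift,
      total_population_max_rel_dev =
        max(abs(baseline$total / targets[seq_along(baseline$total)] - 1)),
      first_year_overall_incidence = baseline$incidence[1] / nondm0
    ),
    iterations = it
  ), class = "calibrated_model")
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat("Calibrated five-state diabetes projection model\n")
  cat(sprintf("  horizon %d-%d; initial population %.1fM\n",
              x$initial$year, x$end_year, sum(x$initial$counts)))
  cat(sprintf("  detection %.4f | diagnosed-at-onset %.4f\n",
              x$params$detection_rate, x$params$diagnosed_at_onset_fraction))
  cat(sprintf("  progression normal->IFG %.4f | IFG->IFG+IGT %.4f\n",
              x$params$prog_normal_to_ifg, x$params$prog_ifg_to_ifgigt))
  cat(sprintf("  base death rate %.4f-%.4f/yr\n",
              min(x$demography$base_death_rate),
              max(x$demography$base_death_rate)))
  cat(sprintf(paste0("  residuals: diagnosed share %.4f | stratum drift %.4f",
                     " | totals %.2e\n"),
              x$residuals$diagnosed_share_max_dev,
              x$residuals$stratum_share_max_drift,
              x$residuals$total_population_max_rel_dev))
  cat(sprintf("  first-year overall incidence %.3f%% of non-diabetic adults\n",
              100 * x$residuals$first_year_overall_incidence))
  invisible(x)
}

#' Run an intervention scenario on a calibrated model
#'
#' Projects the calibrated model under the given scenario, reusing the
#' baseline's solved base-mortality schedule and entrant flows (the census
#' constraint binds the no-intervention run only; scenario totals float
#' with their death counts).
#'
#' @param model A `calibrated_model`.
#' @param scenario An `intervention_scenario`, or a scenario name passed to
#'   [make_scenario()].
#' @param ... Passed to [make_scenario()] when `scenario` is a name.
#' @return A `projection_result`.
#' @export
run_scenario <- function(model, scenario = "none", ...) {
  stopifnot(inherits(model, "calibrated_model"))
  if (is.character(scenario)) {
    scenario <- make_scenario(scenario, start_year = model$initial$year, ...)
  }
  project(model$initial, model$params, model$demography,
          scenario = scenario, end_year = model$end_year)
}

#' Calibrate the background incidence-growth factor
#'
#' For the increasing-incidence sensitivity scenario: finds the constant
#' annual multiplicative trend on incidence such that the no-intervention
#' 2030 prevalence rate (with base mortality re-solved against the same
#' population targets) exceeds the flat-trend projection by
#' `target_increase_pp` percentage points.
#'
#' @param model A flat-trend `calibrated_model`.
#' @param target_increase_pp Percentage-point increase of the horizon
#'   prevalence rate over the flat-trend baseline (default 3.5, the middle
#'   of the three-to-four point range).
#' @return A `calibrated_model` whose parameters carry the solved
#'   `incidence_growth` and whose demography holds the re-solved mortality
#'   schedule.
#' @export
calibrate_incidence_growth <- function(model, target_increase_pp = 3.5) {
  stopifnot(inherits(model, "calibrated_model"))
  flat_rate <- utils::tail(model$baseline$prevalence_rate, 1)
  constrained <- model$demography
  constrained$base_death_rate <- NA_real_
  gap <- function(g) {
    p <- update_parameters(model$params, incidence_growth = g)
    r <- project(model$initial, p, constrained, scenario = NULL,
                 end_year = model$end_year)
    100 * (utils::tail(r$prevalence_rate, 1) - flat_rate) - target_increase_pp
  }
  g <- stats::uniroot(gap, c(1, 1.08), tol = 1e-8)$root
  out <- model
  out$params <- update_parameters(model$params, incidence_growth = g)
  out$baseline <- project(model$initial, out$params, constrained,
                          scenario = NULL, end_year = model$end_year)
  out$demography$base_death_rate <- out$baseline$base_death_rate
  out$residuals$incidence_growth <- g
  out
}
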