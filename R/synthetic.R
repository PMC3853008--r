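#' Specification for synthetic demographic and parameter generation
#'
#' Describes a synthetic stand-in for the census-style demographic schedule
#' and survey-based starting prevalences: a geometric total-population
#' trajectory with optional multiplicative lognormal noise, plus optional
#' jitter on the starting state shares and on the epidemiologic parameters.
#' All generators are pure functions of the spec (including its seed).
#'
#' @param start_year,end_year Horizon covered.
#' @param start_population Total adult population at `start_year`, millions.
#' @param annual_growth Annual population growth fraction (default 0.0094,
#'   the growth rate implied by a 215.5M to 267.4M rise over 23 years).
#' @param growth_noise_sd Standard deviation of the multiplicative lognormal
#'   noise on yearly totals (0 = exactly geometric).
#' @param prevalence_perturbation Relative s.d. of the jitter applied to the
#'   initial state shares by [perturbed_initial_state()].
#' @param parameter_perturbation Relative s.d. of the multiplicative jitter
#'   applied by [generate_parameter_set()].
#' @param seed Integer seed making every generated object reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(start_year = 2007, end_year = 2030,
                           start_population = 215.5,
                           annual_growth = 0.0094,
                           growth_noise_sd = 0,
                           prevalence_perturbation = 0,
                           parameter_perturbation = 0,
                           seed = 1L) {
  stopifnot(end_year > start_year, start_population > 0,
            growth_noise_sd >= 0, prevalence_perturbation >= 0,
            parameter_perturbation >= 0)
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 start_population = start_population,
                 annual_growth = annual_growth,
                 growth_noise_sd = growth_noise_sd,
                 prevalence_perturbation = prevalence_perturbation,
                 parameter_perturbation = parameter_perturbation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_spec_seed <- function(spec, offset, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed + offset)
  expr
}

#' Generate a synthetic demographic schedule
#'
#' Totals follow `start_population * (1 + annual_growth)^t`, multiplied by
#' lognormal noise of s.d. `growth_noise_sd`; entrant flows (births plus
#' migration, split 80/20) are derived so that, at a nominal crude death
#' rate of 1.1%/yr, the totals are reachable.  The base death rate is left
#' unset so the schedule is census-constrained (see
#' [demography_schedule()]), mirroring how the real schedule is used.
#'
#' @param spec A [synthetic_spec()].
#' @return A [demography_schedule()].
#' @export
generate_demography <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  years <- seq.int(spec$start_year, spec$end_year)
  t <- seq_along(years) - 1L
  totals <- with_spec_seed(spec, 0L, {
    noise <- if (spec$growth_noise_sd > 0) {
      exp(stats::rnorm(length(years), 0, spec$growth_noise_sd))
    } else rep(1, length(years))
    spec$start_population * (1 + spec$annual_growth)^t * noise
  })
  nominal_death <- 0.011
  entrants <- c(diff(totals) + nominal_death * totals[-length(totals)], 0)
  entrants[length(entrants)] <- entrants[length(entrants) - 1L]
  demography_schedule(years, totals,
                      births = 0.8 * entrants,
                      migration = 0.2 * entrants)
}

#' Generate a (possibly jittered) epidemiologic parameter set
#'
#' Starts from the base-case parameters (incidence 0.003/0.024/0.039,
#' mortality RRs 1.77/2.11) and applies multiplicative lognormal jitter of
#' relative s.d. `parameter_perturbation`; draws violating the incidence
#' ordering `lambda_normal < lambda_ifg < lambda_ifgigt` are rejected and
#' redrawn.  With zero perturbation the base case is returned exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return An [epi_parameters()] object.
#' @export
generate_parameter_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- epi_parameters()
  if (spec$parameter_perturbation == 0) return(base)
  with_spec_seed(spec, 1L, {
    repeat {
      jitter <- function(v) v * exp(stats::rnorm(1, 0, spec$parameter_perturbation))
      lam <- c(jitter(base$lambda_normal), jitter(base$lambda_ifg),
               jitter(base$lambda_ifgigt))
      if (all(diff(lam) > 0) && all(lam < 1)) break
    }
    update_parameters(base,
                      lambda_normal = lam[1], lambda_ifg = lam[2],
                      lambda_ifgigt = lam[3],
                      rr_undiag = jitter(base$rr_undiag),
                      rr_diag = jitter(base$rr_diag))
  })
}

#' Jittered initial state vector
#'
#' Applies multiplicative lognormal jitter of relative s.d.
#' `prevalence_perturbation` to the default starting state shares, then
#' renormalizes so the counts sum to the spec's starting population.
#'
#' @param spec A [synthetic_spec()].
#' @return A [state_vector()].
#' @export
perturbed_initial_state <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- build_initial_state(
    prevalence_inputs(year = spec$start_year), spec$start_population)
  if (spec$prevalence_perturbation == 0) return(base)
  with_spec_seed(spec, 2L, {
    shares <- base$counts *
      exp(stats::rnorm(n_states(), 0, spec$prevalence_perturbation))
    state_vector(spec$start_year,
                 shares / sum(shares) * spec$start_population)
  })
}

#' Tiny hand-checkable fixture
#'
#' A three-year instance with round numbers used by the oracle-equivalence
#' tests: 100/40/20/10/5 million adults across the five states, incidence
#' 1/2/4% split evenly between diagnosed and undiagnosed at onset,
#' progression 5%/yr, detection 10%/yr, base death rate 1% with mortality
#' RRs 1.5 and 2, and constant entrant flows (1M births, 0.5M migration).
#' The demographic totals are informative only (the schedule carries a
#' fixed death rate, so totals are never solved against).
#'
#' @return List with elements `initial` ([state_vector()]), `params`
#'   ([epi_parameters()]), `demography` ([demography_schedule()]) and
#'   `matrix` (the year-one `transition_matrix`).
#' @export
generate_toy_fixture <- function() {
  params <- epi_parameters(lambda_normal = 0.01, lambda_ifg = 0.02,
                           lambda_ifgigt = 0.04,
                           rr_undiag = 1.5, rr_diag = 2,
                           detection_rate = 0.1,
                           diagnosed_at_onset_fraction = 0.5,
                           prog_normal_to_ifg = 0.05,
                           prog_ifg_to_ifgigt = 0.05)
  initial <- state_vector(2007, c(100, 40, 20, 10, 5))
  demography <- demography_schedule(2007:2010, total = 175,
                                    births = 1, migration = 0.5,
                                    base_death_rate = 0.01)
  list(initial = initial, params = params, demography = demography,
       matrix = build_transition_matrix(params, 0.01, NULL, year = 2007))
}
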