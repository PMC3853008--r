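#' Build the annual five-state transition matrix
#'
#' Assembles the one-year transition probability matrix `P(t)` for a given
#' year.  Structural zeros encode the model's no-remission assumptions: no
#' transition out of diagnosed diabetes except death, and no transition from
#' either diabetes state back to a non-diabetes state.  The non-zero flows
#' are:
#'
#' * progression `NORMAL -> IFG_ONLY` and `IFG_ONLY -> IFG_IGT`;
#' * diabetes incidence out of each non-diabetic state, split between
#'   `UNDIAG_DM` and `DIAG_DM` by the diagnosed-at-onset fraction;
#' * detection `UNDIAG_DM -> DIAG_DM`.
#'
#' Incidence probabilities are scaled by the scenario's per-state multipliers
#' (see [incidence_multipliers()]) and by the background trend
#' `incidence_growth^(year - start_year)`; the probability mass freed by an
#' intervention is returned to the diagonal (people stay in their current
#' state).  Each row sums to one minus that state's annual death probability,
#' where the death probabilities are `base_death_rate` times
#' `(1, 1, 1, rr_undiag, rr_diag)`.
#'
#' @param params An [epi_parameters()] object with all rates resolved
#'   (no `NA`s).
#' @param base_death_rate Annual death probability of the non-diabetic
#'   states, in `[0, 1]`.
#' @param scenario An `intervention_scenario` or `NULL`; interventions apply
#'   only from `scenario$start_year` onward.
#' @param year Calendar year of the transition (the year it starts in).
#' @param start_year Reference year for the incidence-growth trend
#'   (defaults to the scenario start year, else `year`).
#' @return An object of class `transition_matrix`: list with `year`, the
#'   5x5 matrix `p`, and the per-state `death_rates`.
#' @export
build_transition_matrix <- function(params, base_death_rate, scenario = NULL,
                                    year, start_year = NULL) {
  stopifnot(inherits(params, "epi_parameters"))
  if (is.na(base_death_rate) || base_death_rate < 0 || base_death_rate > 1) {
    stop("`base_death_rate` must lie in [0, 1]")
  }
  needed <- c("detection_rate", "diagnosed_at_onset_fraction",
              "prog_normal_to_ifg", "prog_ifg_to_ifgigt")
  if (anyNA(unlist(params[needed]))) {
    stop("parameters contain unresolved NA rates; run calibrate_model() or set them")
  }
  if (is.null(start_year)) {
    start_year <- if (!is.null(scenario)) scenario$start_year else year
  }

  states <- glucose_states()
  mult <- incidence_multipliers(
    if (!is.null(scenario) && year >= scenario$start_year) scenario else NULL)
  growth <- params$incidence_growth^(year - start_year)
  lam <- c(NORMAL = params$lambda_normal,
           IFG_ONLY = params$lambda_ifg,
           IFG_IGT = params$lambda_ifgigt) * growth * mult
  f <- params$diagnosed_at_onset_fraction

  death <- base_death_rate * c(1, 1, 1, params$rr_undiag, params$rr_diag)
  names(death) <- states
  if (any(death > 1)) stop("death probability exceeds 1; base rate infeasible")

  p <- matrix(0, n_states(), n_states(), dimnames = list(states, states))
  p["NORMAL", "IFG_ONLY"] <- params$prog_normal_to_ifg
  p["IFG_ONLY", "IFG_IGT"] <- params$prog_ifg_to_ifgigt
  for (s in nondm_states()) {
    p[s, "UNDIAG_DM"] <- lam[s] * (1 - f)
    p[s, "DIAG_DM"] <- lam[s] * f
  }
  p["UNDIAG_DM", "DIAG_DM"] <- params$detection_rate

  outflow <- rowSums(p)
  diag(p) <- 1 - death - outflow
  if (any(diag(p) < -1e-12)) {
    bad <- states[diag(p) < -1e-12]
    stop("outflow plus death exceeds 1 in state(s): ", paste(bad, collapse = ", "))
  }
  diag(p) <- pmax(diag(p), 0)

  structure(list(year = as.integer(year), p = p, death_rates = death),
            class = "transition_matrix")
}

validate_transition_matrix <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "transition_matrix"))
  p <- m$p
  if (any(p < -tol) || any(p > 1 + tol)) stop("transition probabilities outside [0, 1]")
  if (any(abs(rowSums(p) - (1 - m$death_rates)) > tol)) {
    stop("row sums do not equal 1 - death rate")
  }
  zero_idx <- structural_zero_indices()
  if (any(abs(p[zero_idx]) > tol)) stop("structural zero violated")
  invisible(m)
}

# index matrix of the transitions that can never occur
structural_zero_indices <- function() {
  s <- glucose_states()
  pairs <- rbind(
    c("NORMAL", "IFG_IGT"),
    c("IFG_ONLY", "NORMAL"),
    c("IFG_IGT", "NORMAL"), c("IFG_IGT", "IFG_ONLY"),
    c("UNDIAG_DM", "NORMAL"), c("UNDIAG_DM", "IFG_ONLY"), c("UNDIAG_DM", "IFG_IGT"),
    c("DIAG_DM", "NORMAL"), c("DIAG_DM", "IFG_ONLY"), c("DIAG_DM", "IFG_IGT"),
    c("DIAG_DM", "UNDIAG_DM"))
  cbind(match(pairs[, 1], s), match(pairs[, 2], s))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Annual transition matrix, year", x$year, "\n")
  print(round(x$p, 5))
  cat("death rates:", paste(sprintf("%.5f", x$death_rates), collapse = " "), "\n")
  invisible(x)
}

#' Advance the population one year
#'
#' Applies the difference equation `N(t) = N(t-1) P(t) + B(t) + M(t)`:
#' the current state vector is propagated through the transition matrix and
#' the per-state birth and net-migration inflows are added.
#'
#' @param state A [state_vector()] for year `t - 1`.
#' @param matrix A `transition_matrix` for the transition starting in
#'   `state$year`.
#' @param births Per-state inflow of new adults (millions); scalar 0 allowed.
#' @param migration Per-state net migration (millions); scalar 0 allowed.
#' @return The [state_vector()] for the next year.
#' @export
step <- function(state, matrix, births = 0, migration = 0) {
  stopifnot(inherits(state, "state_vector"), inherits(matrix, "transition_matrix"))
  if (matrix$year != state$year) {
    stop("transition matrix year (", matrix$year,
         ") must equal the state year (", state$year, ")")
  }
  expand <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, n_states())
    if (length(v) != n_states()) stop("`", what, "` must have length 1 or 5")
    v
  }
  births <- expand(births, "births")
  migration <- expand(migration, "migration")
  counts <- as.vector(state$counts %*% matrix$p) + births + migration
  if (any(counts < -1e-9)) {
    stop("negative population count after step; demography inconsistent")
  }
  state_vector(state$year + 1L, pmax(counts, 0))
}
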