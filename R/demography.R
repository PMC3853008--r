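#' Demographic schedule for the projection horizon
#'
#' Holds, per transition year, the total-population target (millions), the
#' inflow of new adults ("births", entering the NORMAL state), net migration
#' (allocated proportionally to the current state mix), and the base annual
#' death probability of the non-diabetic states.
#'
#' When `base_death_rate` is `NA` the schedule is *census-constrained*:
#' [project()] solves the base rate each year in closed form so that the
#' projected total matches `total` exactly (deaths close the demographic
#' identity).  After a calibrated baseline run the solved rates can be
#' written back with [solve_base_mortality()] / [calibrate_model()], giving
#' a fixed schedule that intervention runs share.
#'
#' @param years Calendar years covered (first projection year through the
#'   horizon).
#' @param total Total adult population target per year, millions.
#' @param births Annual inflow of new adults, millions (recycled).
#' @param migration Annual net migration, millions (recycled).
#' @param base_death_rate Annual death probability for non-diabetic states
#'   per year, or `NA` to solve it against the totals.
#' @return An object of class `demography_schedule` (a data frame).
#' @export
demography_schedule <- function(years, total, births = 0, migration = 0,
                                base_death_rate = NA_real_) {
  years <- as.integer(years)
  n <- length(years)
  stopifnot(n >= 2L, all(diff(years) == 1L))
  total <- rep_len(as.numeric(total), n)
  if (any(!is.finite(total)) || any(total <= 0)) {
    stop("population totals must be finite and strictly positive")
  }
  out <- data.frame(
    year = years,
    total = total,
    births = rep_len(as.numeric(births), n),
    migration = rep_len(as.numeric(migration), n),
    base_death_rate = rep_len(as.numeric(base_death_rate), n)
  )
  class(out) <- c("demography_schedule", "data.frame")
  out
}

demography_row <- function(demography, year) {
  i <- match(year, demography$year)
  if (is.na(i)) {
    stop("demography schedule does not cover year ", year)
  }
  demography[i, , drop = FALSE]
}

is_constrained <- function(demography) anyNA(demography$base_death_rate)
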