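#' Epidemiologic parameters of the five-state model
#'
#' Bundles the annual transition-rate parameters that drive the projection:
#' per-stratum diabetes incidence, prediabetes progression, detection of
#' undiagnosed diabetes, mortality relative risks, and an optional
#' multiplicative background trend on incidence.
#'
#' The default incidence and mortality values are the model's base case:
#' annual diabetes incidence of 0.3% from normal glycaemia, 2.4% from IFG
#' without IGT and 3.9% from combined IFG and IGT (population-average about
#' 1.22%/yr), and mortality relative risks versus no diabetes of 1.77 for
#' undiagnosed and 2.11 for diagnosed diabetes.  Detection, diagnosed-at-onset
#' and progression rates are not observed directly; they are solved by
#' [calibrate_model()] and default to `NA` until then.
#'
#' @param lambda_normal Annual probability of developing diabetes from the
#'   NORMAL state.
#' @param lambda_ifg Annual diabetes incidence from IFG_ONLY.
#' @param lambda_ifgigt Annual diabetes incidence from IFG_IGT.
#' @param overall_incidence Population-average annual diabetes incidence used
#'   as a validation check (never fitted).
#' @param rr_undiag,rr_diag Mortality relative risks for undiagnosed and
#'   diagnosed diabetes versus the non-diabetic states.
#' @param detection_rate Annual probability that undiagnosed diabetes is
#'   diagnosed (UNDIAG_DM to DIAG_DM).
#' @param diagnosed_at_onset_fraction Share of incident diabetes entering
#'   DIAG_DM directly rather than UNDIAG_DM.
#' @param prog_normal_to_ifg Annual NORMAL to IFG_ONLY progression probability.
#' @param prog_ifg_to_ifgigt Annual IFG_ONLY to IFG_IGT progression probability.
#' @param incidence_growth Annual multiplicative trend applied to all
#'   incidence rates; 1 encodes the flat-trend background scenario.
#' @return An object of class `epi_parameters` (a named list).
#' @export
epi_parameters <- function(lambda_normal = 0.003,
                           lambda_ifg = 0.024,
                           lambda_ifgigt = 0.039,
                           overall_incidence = 0.0122,
                           rr_undiag = 1.77,
                           rr_diag = 2.11,
                           detection_rate = NA_real_,
                           diagnosed_at_onset_fraction = NA_real_,
                           prog_normal_to_ifg = NA_real_,
                           prog_ifg_to_ifgigt = NA_real_,
                           incidence_growth = 1) {
  p <- list(lambda_normal = lambda_normal,
            lambda_ifg = lambda_ifg,
            lambda_ifgigt = lambda_ifgigt,
            overall_incidence = overall_incidence,
            rr_undiag = rr_undiag,
            rr_diag = rr_diag,
            detection_rate = detection_rate,
            diagnosed_at_onset_fraction = diagnosed_at_onset_fraction,
            prog_normal_to_ifg = prog_normal_to_ifg,
            prog_ifg_to_ifgigt = prog_ifg_to_ifgigt,
            incidence_growth = incidence_growth)
  validate_epi_parameters(p)
  structure(p, class = "epi_parameters")
}

validate_epi_parameters <- function(p) {
  probs <- c("lambda_normal", "lambda_ifg", "lambda_ifgigt",
             "detection_rate", "diagnosed_at_onset_fraction",
             "prog_normal_to_ifg", "prog_ifg_to_ifgigt")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop(sprintf("`%s` must lie in [0, 1] (got %g)", nm, v))
    }
  }
  if (p$rr_undiag <= 0 || p$rr_diag <= 0) stop("mortality relative risks must be positive")
  if (p$incidence_growth <= 0) stop("`incidence_growth` must be positive")
  lam <- c(p$lambda_normal, p$lambda_ifg, p$lambda_ifgigt)
  # strict risk ordering, except in the degenerate no-incidence case
  if (any(lam > 0) && !all(diff(lam) > 0)) {
    stop("incidence must be ordered: lambda_normal < lambda_ifg < lambda_ifgigt")
  }
  invisible(p)
}

#' Update epidemiologic parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params An `epi_parameters` object.
#' @param ... Named fields to replace.
#' @return The modified `epi_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "epi_parameters"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  params[names(dots)] <- dots
  validate_epi_parameters(params)
  structure(params, class = "epi_parameters")
}

#' @export
print.epi_parameters <- function(x, ...) {
  cat("Epidemiologic parameters (annual probabilities)\n")
  cat(sprintf("  diabetes incidence: normal %.4f | IFG %.4f | IFG+IGT %.4f\n",
              x$lambda_normal, x$lambda_ifg, x$lambda_ifgigt))
  cat(sprintf("  mortality RR: undiagnosed %.2f | diagnosed %.2f\n",
              x$rr_undiag, x$rr_diag))
  cat(sprintf("  detection %.4f | diagnosed-at-onset %.4f\n",
              x$detection_rate, x$diagnosed_at_onset_fraction))
  cat(sprintf("  progression: normal->IFG %.4f | IFG->IFG+IGT %.4f\n",
              x$prog_normal_to_ifg, x$prog_ifg_to_ifgigt))
  cat(sprintf("  incidence growth factor %.4f/yr\n", x$incidence_growth))
  invisible(x)
}
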