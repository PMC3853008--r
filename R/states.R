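#' Glucose-tolerance states of the model
#'
#' The model partitions the US adult population into five mutually exclusive
#' glucose-tolerance states: normal glycaemia, impaired fasting glucose
#' without impaired glucose tolerance (`IFG_ONLY`), impaired fasting glucose
#' together with impaired glucose tolerance (`IFG_IGT`), undiagnosed
#' diabetes, and diagnosed diabetes.  `IFG_ONLY` and `IFG_IGT` partition the
#' pool of adults with IFG regardless of IGT status.
#'
#' @return `glucose_states()` returns the five state labels in model order;
#'   `dm_states()` and `nondm_states()` return the diabetes and non-diabetes
#'   subsets.
#' @export
glucose_states <- function() {
  c("NORMAL", "IFG_ONLY", "IFG_IGT", "UNDIAG_DM", "DIAG_DM")
}

#' @rdname glucose_states
#' @export
dm_states <- function() c("UNDIAG_DM", "DIAG_DM")

#' @rdname glucose_states
#' @export
nondm_states <- function() c("NORMAL", "IFG_ONLY", "IFG_IGT")

n_states <- function() 5L

#' Population state vector
#'
#' Counts of adults (in millions) in each glucose-tolerance state at the
#' start of a calendar year.
#'
#' @param year Calendar year the counts refer to.
#' @param counts Numeric vector of length 5, in millions, ordered as
#'   [glucose_states()]; names are attached if missing.
#' @return An object of class `state_vector`: a list with elements `year`
#'   and `counts` (named, millions).
#' @export
state_vector <- function(year, counts) {
  stopifnot(length(year) == 1L, is.finite(year))
  counts <- as.numeric(counts)
  if (length(counts) != n_states()) {
    stop("`counts` must have exactly five entries, one per glucose state")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("state counts must be finite and non-negative")
  }
  names(counts) <- glucose_states()
  structure(list(year = as.integer(year), counts = counts),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat("Population state vector, year ", x$year,
      " (total ", format(round(sum(x$counts), 3)), " million)\n", sep = "")
  print(round(x$counts, 4))
  invisible(x)
}

#' @export
format.state_vector <- function(x, ...) {
  paste0(x$year, ": ", paste(sprintf("%s=%.3f", names(x$counts), x$counts),
                             collapse = ", "))
}
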