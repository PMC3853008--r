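#' Run the projection model over an effectiveness design
#'
#' Runs the full projection once per design point and records the reduction
#' in horizon-year diabetes prevalence versus no intervention.  The design
#' covers the scenario family's *active* effectiveness predictors: targeted
#' effectiveness `x1` for the lifestyle families (`high_risk`,
#' `moderate_risk`), population-wide effectiveness `x2` for `population`,
#' and a full factorial over both for `combined`.  Defaults are five
#' log-spaced values spanning half to double the base-case effectiveness
#' (0.0625-0.25 for `x1`, 0.01-0.04 for `x2`).
#'
#' These runs are the "sample" to which the log-linear emulator is fitted;
#' all values must be strictly positive so their logarithms exist.
#'
#' @param model A `calibrated_model`.
#' @param family Scenario family: `"high_risk"`, `"moderate_risk"`,
#'   `"population"` or `"combined"`.
#' @param x1_values Targeted-effectiveness design values (fractions).
#' @param x2_values Population-wide-effectiveness design values.
#' @return An object of class `emulator_runs`: data frame with columns
#'   `x1`, `x2` (NA when inactive) and `y` (millions of prevalent cases
#'   averted at the horizon).
#' @export
design_runs <- function(model,
                        family = c("combined", "moderate_risk", "high_risk",
                                   "population"),
                        x1_values = exp(seq(log(0.0625), log(0.25),
                                            length.out = 5)),
                        x2_values = exp(seq(log(0.01), log(0.04),
                                            length.out = 5))) {
  stopifnot(inherits(model, "calibrated_model"))
  family <- match.arg(family)
  active <- switch(family,
                   high_risk = "x1", moderate_risk = "x1",
                   population = "x2", combined = c("x1", "x2"))
  if ("x1" %in% active) {
    if (length(unique(x1_values)) < 3) stop("need >= 3 distinct x1 values")
    if (any(x1_values <= 0)) stop("design values must be strictly positive")
  }
  if ("x2" %in% active) {
    if (length(unique(x2_values)) < 3) stop("need >= 3 distinct x2 values")
    if (any(x2_values <= 0)) stop("design values must be strictly positive")
  }
  grid <- switch(family,
    combined = expand.grid(x1 = x1_values, x2 = x2_values),
    population = data.frame(x1 = NA_real_, x2 = x2_values),
    data.frame(x1 = x1_values, x2 = NA_real_))
  if (nrow(grid) < length(active) + 2L) {
    stop("fewer runs than predictors + 2; design too small to fit")
  }

  none <- run_scenario(model, "none")
  base_prev <- utils::tail(none$prevalence_millions, 1)
  grid$y <- vapply(seq_len(nrow(grid)), function(i) {
    sc <- make_scenario(family,
                        targeted_eff = if (is.na(grid$x1[i])) 0.125 else grid$x1[i],
                        population_eff = if (is.na(grid$x2[i])) 0.02 else grid$x2[i],
                        start_year = model$initial$year)
    r <- run_scenario(model, sc)
    base_prev - utils::tail(r$prevalence_millions, 1)
  }, numeric(1))
  structure(grid, class = c("emulator_runs", "data.frame"),
            family = family, active = active)
}

#' Fit the log-linear run emulator
#'
#' Ordinary least squares of the projected prevalence reduction `y` on the
#' natural logarithms of the active effectiveness predictors,
#' `y ~ ln(x1) + ln(x2)`.  The fitted surface is the cheap surrogate used
#' for error propagation in place of a full Monte-Carlo sweep of the
#' projection model.
#'
#' @param runs An `emulator_runs` object from [design_runs()].
#' @return An object of class `emulator_fit` with the coefficients,
#'   `r_squared`, `residual_sd` (millions) and the underlying `lm` fit.
#' @export
fit_emulator <- function(runs) {
  stopifnot(inherits(runs, "emulator_runs"))
  active <- attr(runs, "active")
  df <- as.data.frame(runs)
  df$lnx1 <- log(df$x1)
  df$lnx2 <- log(df$x2)
  form <- stats::as.formula(paste(
    "y ~", paste(sub("x", "lnx", active), collapse = " + ")))
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("design is collinear or degenerate; emulator not identifiable")
  }
  s <- summary(fit)
  structure(list(
    family = attr(runs, "family"),
    active = active,
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    coef_lnx1 = if ("x1" %in% active) unname(stats::coef(fit)[["lnx1"]]) else NA_real_,
    coef_lnx2 = if ("x2" %in% active) unname(stats::coef(fit)[["lnx2"]]) else NA_real_,
    r_squared = s$r.squared,
    residual_sd = s$sigma,
    lm = fit
  ), class = "emulator_fit")
}

#' Predict a prevalence reduction from the emulator
#'
#' @param fit An `emulator_fit`.
#' @param x1,x2 Effectiveness values (only the fit's active predictors are
#'   used; both must be positive where active).
#' @return Predicted reduction in horizon-year prevalent cases, millions.
#' @export
predict_emulator <- function(fit, x1 = NA, x2 = NA) {
  stopifnot(inherits(fit, "emulator_fit"))
  out <- fit$intercept
  if ("x1" %in% fit$active) {
    if (any(is.na(x1) | x1 <= 0)) stop("x1 must be positive for this fit")
    out <- out + fit$coef_lnx1 * log(x1)
  }
  if ("x2" %in% fit$active) {
    if (any(is.na(x2) | x2 <= 0)) stop("x2 must be positive for this fit")
    out <- out + fit$coef_lnx2 * log(x2)
  }
  out
}

#' @export
print.emulator_fit <- function(x, ...) {
  cat(sprintf("Log-linear emulator, %s family (r^2 = %.3f)\n",
              x$family, x$r_squared))
  cat(sprintf("  y = %.4f", x$intercept))
  if ("x1" %in% x$active) cat(sprintf(" + %.4f ln(x1)", x$coef_lnx1))
  if ("x2" %in% x$active) cat(sprintf(" + %.4f ln(x2)", x$coef_lnx2))
  cat(sprintf("  [residual sd %.4f]\n", x$residual_sd))
  invisible(x)
}

#' Subjective distribution over an intervention effectiveness
#'
#' Specifies the uncertainty placed on an effectiveness fraction for error
#' propagation.  The default is a lognormal with median at the base case
#' and 2.5th/97.5th percentiles at half and double the median — the same
#' span as the one-variable-at-a-time sensitivity analyses.  A `point`
#' distribution fixes the value exactly.  Only strictly positive families
#' are allowed because the emulator works on log-effectiveness.
#'
#' @param median Central value (median) of the effectiveness.
#' @param family `"lognormal"` or `"point"`.
#' @param lower,upper 2.5th and 97.5th percentiles (lognormal only).
#' @return An object of class `effect_distribution`.
#' @export
effect_distribution <- function(median, family = c("lognormal", "point"),
                                lower = median / 2, upper = 2 * median) {
  family <- match.arg(family)
  if (median <= 0) stop("effectiveness distribution must be strictly positive")
  if (family == "lognormal") {
    if (lower <= 0 || upper <= lower) stop("need 0 < lower < upper")
    sdlog <- (log(upper) - log(median)) / stats::qnorm(0.975)
  } else {
    sdlog <- 0
  }
  structure(list(family = family, median = median,
                 meanlog = log(median), sdlog = sdlog),
            class = "effect_distribution")
}

sample_effect <- function(dist, n) {
  stopifnot(inherits(dist, "effect_distribution"))
  if (dist$family == "point") rep(dist$median, n)
  else stats::rlnorm(n, dist$meanlog, dist$sdlog)
}

#' Propagate effectiveness uncertainty through the emulator
#'
#' Monte-Carlo error propagation: draws effectiveness values from the
#' subjective distributions, evaluates the emulator at each draw, adds
#' residual noise (so the interval covers the model output, not just its
#' mean), and reports the empirical 2.5th/97.5th percentiles truncated
#' below at zero.
#'
#' @param fit An `emulator_fit`.
#' @param x1_dist,x2_dist [effect_distribution()]s for the active
#'   predictors (required where active).
#' @param n_samples Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return An object of class `credibility_interval`: list with `lower`,
#'   `upper` (millions), `level` (0.95) and the sample mean.
#' @export
propagate <- function(fit, x1_dist = NULL, x2_dist = NULL,
                      n_samples = 10000, seed = 1) {
  stopifnot(inherits(fit, "emulator_fit"))
  if (n_samples < 1000) stop("`n_samples` must be at least 1000")
  if ("x1" %in% fit$active && is.null(x1_dist)) stop("x1_dist required for this fit")
  if ("x2" %in% fit$active && is.null(x2_dist)) stop("x2_dist required for this fit")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  pred <- rep(fit$intercept, n_samples)
  if ("x1" %in% fit$active) {
    pred <- pred + fit$coef_lnx1 * log(sample_effect(x1_dist, n_samples))
  }
  if ("x2" %in% fit$active) {
    pred <- pred + fit$coef_lnx2 * log(sample_effect(x2_dist, n_samples))
  }
  if (fit$residual_sd > 0) {
    pred <- pred + stats::rnorm(n_samples, 0, fit$residual_sd)
  }
  q <- stats::quantile(pred, c(0.025, 0.975), names = FALSE)
  structure(list(lower = max(0, q[1]), upper = max(0, q[2]),
                 level = 0.95, mean = mean(pred),
                 n_samples = n_samples, seed = seed),
            class = "credibility_interval")
}

#' @export
print.credibility_interval <- function(x, ...) {
  cat(sprintf("%.0f%% approximate credibility interval: %.1f to %.1f million (mean %.1f)\n",
              100 * x$level, x$lower, x$upper, x$mean))
  invisible(x)
}

#' Emulator-based uncertainty table for all intervention families
#'
#' For each scenario family: runs the effectiveness design, fits the
#' log-linear emulator, and propagates the default subjective effectiveness
#' distributions (lognormal, median at base case, half/double at the 2.5th
#' and 97.5th percentiles) into an approximate 95% credibility interval for
#' the reduction in horizon-year diabetes prevalence.
#'
#' @param model A `calibrated_model`.
#' @param families Scenario families to tabulate.
#' @param targeted_median,population_median Medians of the subjective
#'   effectiveness distributions.
#' @param n_samples Monte-Carlo draws per family.
#' @param seed Base integer seed (incremented per family).
#' @return Data frame with columns `scenario`, `r_squared`, `lower`,
#'   `upper` (millions).
#' @export
uncertainty_table <- function(model,
                              families = c("combined", "population",
                                           "high_risk", "moderate_risk"),
                              targeted_median = 0.125,
                              population_median = 0.02,
                              n_samples = 10000, seed = 1) {
  x1d <- effect_distribution(targeted_median)
  x2d <- effect_distribution(population_median)
  rows <- lapply(seq_along(families), function(i) {
    fam <- families[i]
    fit <- fit_emulator(design_runs(model, fam))
    ci <- propagate(fit, x1_dist = x1d, x2_dist = x2d,
                    n_samples = n_samples, seed = seed + i - 1L)
    data.frame(scenario = fam, r_squared = fit$r_squared,
               lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
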