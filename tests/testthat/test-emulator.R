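# construct an emulator_runs object directly (bypassing the projection) so
# the fitting and propagation machinery can be checked against known truths
synthetic_runs <- function(x1, y, x2 = NA_real_, active = "x1",
                           family = "moderate_risk") {
  structure(data.frame(x1 = x1, x2 = x2, y = y),
            class = c("emulator_runs", "data.frame"),
            family = family, active = active)
}

test_that("exactly log-linear runs are recovered perfectly", {
  x1 <- exp(seq(log(0.05), log(0.4), length.out = 7))
  runs <- synthetic_runs(x1, y = 2 + 0.5 * log(x1))
  fit <- suppressWarnings(fit_emulator(runs))  # exact fit warns harmlessly
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$coef_lnx1, 0.5, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
  expect_equal(predict_emulator(fit, x1 = 0.1), 2 + 0.5 * log(0.1))
})

test_that("residual noise of known size is estimated from the runs", {
  set.seed(7)
  x1 <- stats::runif(50, 0.05, 0.4)
  y <- 2 + 0.5 * log(x1) + stats::rnorm(50, 0, 0.1)
  fit <- fit_emulator(synthetic_runs(x1, y))
  expect_gt(fit$residual_sd, 0.07)
  expect_lt(fit$residual_sd, 0.13)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_emulator(synthetic_runs(rep(0.1, 5), y = rep(1, 5))),
               "collinear|degenerate")
})

test_that("design runs grow monotonically with targeted effectiveness", {
  m <- test_model()
  runs <- design_runs(m, "moderate_risk", x1_values = c(0.0625, 0.125, 0.25))
  expect_equal(nrow(runs), 3)
  expect_true(all(diff(runs$y[order(runs$x1)]) > 0))
  # the base-case design point reproduces the direct moderate-risk effect
  expect_equal(runs$y[runs$x1 == 0.125], 3.1, tolerance = 0.05)
})

test_that("design validation enforces positivity, size and run count", {
  m <- test_model()
  expect_error(design_runs(m, "moderate_risk", x1_values = c(0.1, 0.2)),
               ">= 3 distinct")
  expect_error(design_runs(m, "moderate_risk", x1_values = c(0, 0.1, 0.2)),
               "strictly positive")
  expect_error(design_runs(m, "population", x2_values = c(0.01, 0.02)),
               ">= 3 distinct")
})

test_that("the factorial combined design fits well with a log-linear surface", {
  m <- test_model()
  fit <- fit_emulator(design_runs(m, "combined"))
  expect_gte(fit$r_squared, 0.85)
  # emulator prediction at the base case agrees with the direct model run
  none <- base_runs()$none
  direct <- utils::tail(none$prevalence_millions, 1) -
    utils::tail(base_runs()$combined$prevalence_millions, 1)
  pred <- predict_emulator(fit, x1 = 0.125, x2 = 0.02)
  expect_lt(abs(pred - direct), 2 * max(fit$residual_sd, 1e-6))
})

test_that("point-mass distributions with zero residual collapse the interval", {
  x1 <- exp(seq(log(0.05), log(0.4), length.out = 5))
  fit <- suppressWarnings(fit_emulator(synthetic_runs(x1, y = 2 + 0.5 * log(x1))))
  ci <- propagate(fit, x1_dist = effect_distribution(0.125, "point"),
                  n_samples = 1000, seed = 1)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, predict_emulator(fit, x1 = 0.125))
})

test_that("propagation matches the closed-form lognormal-linear quantiles", {
  x1 <- exp(seq(log(0.05), log(0.4), length.out = 5))
  fit <- suppressWarnings(fit_emulator(synthetic_runs(x1, y = 2 + 0.5 * log(x1))))
  dist <- effect_distribution(0.125)   # half/double at the 2.5/97.5 centiles
  ci <- propagate(fit, x1_dist = dist, n_samples = 50000, seed = 42)
  # y = a + b ln(x1) with ln(x1) normal: y is normal with known quantiles
  mu <- 2 + 0.5 * log(0.125)
  sd <- 0.5 * log(2) / stats::qnorm(0.975)
  expect_equal(ci$lower, mu - stats::qnorm(0.975) * sd, tolerance = 0.02)
  expect_equal(ci$upper, mu + stats::qnorm(0.975) * sd, tolerance = 0.02)
})

test_that("propagation is bit-reproducible given the seed", {
  m <- test_model()
  fit <- fit_emulator(design_runs(m, "combined"))
  d1 <- effect_distribution(0.125); d2 <- effect_distribution(0.02)
  ci1 <- propagate(fit, d1, d2, n_samples = 2000, seed = 99)
  ci2 <- propagate(fit, d1, d2, n_samples = 2000, seed = 99)
  expect_identical(ci1, ci2)
  ci3 <- propagate(fit, d1, d2, n_samples = 2000, seed = 100)
  expect_false(identical(ci1$lower, ci3$lower))
})

test_that("wider subjective uncertainty widens the credibility interval", {
  x1 <- exp(seq(log(0.05), log(0.4), length.out = 5))
  fit <- suppressWarnings(fit_emulator(synthetic_runs(x1, y = 2 + 0.5 * log(x1))))
  narrow <- propagate(fit, effect_distribution(0.125, lower = 0.1, upper = 0.15),
                      n_samples = 5000, seed = 3)
  wide <- propagate(fit, effect_distribution(0.125, lower = 0.05, upper = 0.3),
                    n_samples = 5000, seed = 3)
  expect_gt(wide$upper - wide$lower, narrow$upper - narrow$lower)
})

test_that("distributions admitting non-positive effectiveness are rejected", {
  expect_error(effect_distribution(-0.1), "positive")
  expect_error(effect_distribution(0.125, lower = 0), "lower")
})

test_that("the uncertainty table covers all families with sound fits", {
  m <- test_model()
  tab <- uncertainty_table(m, n_samples = 2000, seed = 5)
  expect_equal(tab$scenario,
               c("combined", "population", "high_risk", "moderate_risk"))
  expect_true(all(tab$r_squared >= 0.85))
  expect_true(all(tab$lower >= 0))
  expect_true(all(tab$upper > tab$lower))
})
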