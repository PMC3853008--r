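test_that("net effectiveness is the product of the cascade fractions", {
  expect_identical(net_effectiveness(0.5, 0.5, 0.5), 0.125)
  expect_identical(net_effectiveness(1, 1, 1), 1)
  expect_identical(net_effectiveness(0.5, 0.5, 0.25), 0.0625)
  expect_error(net_effectiveness(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("scenario constructors encode the right targets and multipliers", {
  none <- make_scenario("none")
  expect_equal(none$targeted_effectiveness, 0)
  expect_equal(none$population_effectiveness, 0)
  expect_equal(unname(incidence_multipliers(none)), rep(1, 3))

  high <- make_scenario("high_risk")
  expect_equal(high$target_states, "IFG_IGT")
  expect_equal(unname(incidence_multipliers(high)), c(1, 1, 0.875))

  mod <- make_scenario("moderate_risk")
  expect_setequal(mod$target_states, c("IFG_ONLY", "IFG_IGT"))

  pop <- make_scenario("population")
  expect_equal(unname(incidence_multipliers(pop)), rep(0.98, 3))

  comb <- make_scenario("combined")
  expect_equal(unname(incidence_multipliers(comb)),
               c(0.98, 0.875 * 0.98, 0.875 * 0.98))

  expect_error(make_scenario("universal"))
})

test_that("relative attenuation reproduces the published table arithmetic", {
  # prevalence rate rising 12.9% -> 22.7% (none) vs 12.9% -> 21.3% (combined)
  none <- fake_result(2007:2030, c(0.129, rep(NA, 22), 0.227),
                      c(27.8, rep(NA, 22), 60.7))
  comb <- fake_result(2007:2030, c(0.129, rep(NA, 22), 0.213),
                      c(27.8, rep(NA, 22), 57.1))
  expect_equal(relative_attenuation(none, comb, "rate"),
               100 * (9.8 - 8.4) / 9.8, tolerance = 1e-10)
  expect_equal(relative_attenuation(none, comb, "rate"), 14.3,
               tolerance = 1e-2)
  # counts: 32.9 vs 29.8 million increase under the moderate-risk strategy
  mod <- fake_result(2007:2030, c(0.129, rep(NA, 22), 0.215),
                     c(27.8, rep(NA, 22), 57.6))
  expect_equal(relative_attenuation(none, mod, "count"),
               100 * (32.9 - 29.8) / 32.9, tolerance = 1e-10)
  # identical runs attenuate nothing
  expect_equal(relative_attenuation(none, none), 0)
  # zero baseline change is undefined
  flat <- fake_result(2007:2030, rep(0.1, 24), rep(20, 24))
  expect_error(relative_attenuation(flat, comb), "zero")
})

test_that("scenario comparison requires the baseline and nulls out self-comparison", {
  runs <- base_runs()
  expect_error(compare_scenarios(runs[c("combined", "population")]),
               "no-intervention")
  cmp <- compare_scenarios(runs["none"])
  expect_equal(cmp$prevented_cumulative_cases, 0)
  expect_equal(cmp$prevented_prevalent_cases, 0)
})

test_that("2030 prevalence orders combined <= moderate <= high <= none", {
  cmp <- compare_scenarios(base_runs())
  prev <- stats::setNames(cmp$prevalent_millions, cmp$scenario)
  expect_lte(prev[["combined"]], prev[["moderate_risk"]])
  expect_lte(prev[["moderate_risk"]], prev[["high_risk"]])
  expect_lte(prev[["high_risk"]], prev[["none"]])
  expect_lte(prev[["combined"]],
             min(prev[["moderate_risk"]], prev[["population"]]))
})

test_that("prevented prevalent cases never exceed prevented incident cases", {
  cmp <- compare_scenarios(base_runs())
  expect_true(all(cmp$prevented_prevalent_cases <=
                    cmp$prevented_cumulative_cases + 1e-12))
})

test_that("prevented cases increase monotonically with effectiveness", {
  m <- test_model()
  none <- base_runs()$none
  prevented <- vapply(c(0.05, 0.125, 0.25), function(e) {
    r <- run_scenario(m, make_scenario("moderate_risk", targeted_eff = e,
                                       start_year = m$initial$year))
    utils::tail(none$cumulative_incidence, 1) -
      utils::tail(r$cumulative_incidence, 1)
  }, numeric(1))
  expect_true(all(diff(prevented) > 0))
})

test_that("small effectiveness scales prevented cases approximately linearly", {
  m <- test_model()
  none <- base_runs()$none
  prevented <- function(e) {
    r <- run_scenario(m, make_scenario("moderate_risk", targeted_eff = e,
                                       start_year = m$initial$year))
    utils::tail(none$prevalence_millions, 1) -
      utils::tail(r$prevalence_millions, 1)
  }
  ratio <- prevented(0.02) / prevented(0.01)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("targeting the larger IFG pool prevents more cases than IFG+IGT alone", {
  m <- test_model()
  none <- base_runs()$none
  last <- length(none$years)
  prevented <- function(name) {
    r <- run_scenario(m, make_scenario(name, targeted_eff = 0.125,
                                       start_year = m$initial$year))
    none$cumulative_incidence[last] - r$cumulative_incidence[last]
  }
  expect_gt(prevented("moderate_risk"), prevented("high_risk"))
})

test_that("sensitivity analysis varies one assumption at a time", {
  m <- test_model()
  sens <- sensitivity_analysis(m, targeted_values = 0.25,
                               population_values = 0.04,
                               increasing_background = FALSE)
  expect_setequal(unique(sens$assumption),
                  c("base_case", "targeted_eff_0.25", "population_eff_0.04"))
  base <- sens[sens$assumption == "base_case", ]
  dbl <- sens[sens$assumption == "targeted_eff_0.25", ]
  # doubling targeted effectiveness must not change the population strategy
  expect_equal(dbl$prevented_prevalent_millions[dbl$scenario == "population"],
               base$prevented_prevalent_millions[base$scenario == "population"])
  # but must strengthen the moderate-risk strategy
  expect_gt(dbl$prevented_prevalent_millions[dbl$scenario == "moderate_risk"],
            base$prevented_prevalent_millions[base$scenario == "moderate_risk"])
})
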