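test_that("population targets are back-derived from count/rate anchors", {
  targets <- derive_population_targets(default_anchors())
  expect_equal(targets[["2007"]], 27.8 / 0.129, tolerance = 1e-12)
  expect_equal(targets[["2030"]], 60.7 / 0.227, tolerance = 1e-12)
  expect_equal(unname(targets[["2007"]]), 215.50388, tolerance = 1e-6)
  expect_equal(unname(targets[["2030"]]), 267.40088, tolerance = 1e-6)
  # geometric interpolation is monotone between increasing anchors
  expect_true(all(diff(targets) > 0))

  flat <- derive_population_targets(
    data.frame(year = c(2007, 2010), count = c(30, 30), rate = c(0.1, 0.1)))
  expect_equal(unname(flat), rep(300, 4))

  expect_error(derive_population_targets(
    data.frame(year = c(2007, 2010), count = c(30, 30), rate = c(0, 0.1))),
    "strictly positive")
})

test_that("initial state reproduces the starting prevalences exactly", {
  inp <- prevalence_inputs()
  s <- build_initial_state(inp, 215.5)
  expect_equal(sum(s$counts), 215.5)
  expect_equal(sum(s$counts[dm_states()]) / sum(s$counts), 0.129)
  expect_equal(unname(s$counts["IFG_ONLY"] / 215.5), 0.267 - 0.083)
  expect_equal(unname(s$counts["NORMAL"] / 215.5), 1 - 0.129 - 0.267)

  all_diag <- build_initial_state(
    prevalence_inputs(diagnosed_share_of_dm = 1), 100)
  expect_equal(unname(all_diag$counts["UNDIAG_DM"]), 0)

  expect_error(prevalence_inputs(ifg_igt_rate = 0.3, ifg_rate_any = 0.2))
})

test_that("base mortality inverts the weighted death-rate average", {
  # 90% of the population without diabetes, 10% diagnosed (RR 2.11),
  # crude death rate 1%: base = 0.01 / (0.9 + 0.1 * 2.11)
  params <- epi_parameters()
  counts <- matrix(c(90, 0, 0, 0, 10,
                     90, 0, 0, 0, 10), 2, 5, byrow = TRUE,
                   dimnames = list(2007:2008, glucose_states()))
  res <- structure(list(years = 2007:2008, counts = counts),
                   class = "projection_result")
  dem <- demography_schedule(2007:2008, total = c(100, 99),
                             births = 0, migration = 0)
  rates <- solve_base_mortality(dem, params, res)
  expect_equal(unname(rates[1]), 0.01 / (0.9 + 0.1 * 2.11), tolerance = 1e-12)
  expect_equal(unname(rates[1]), 0.00900, tolerance = 1e-3)

  # with both RRs at 1 the base rate is the crude rate itself
  p1 <- update_parameters(params, rr_undiag = 1, rr_diag = 1)
  expect_equal(unname(solve_base_mortality(dem, p1, res)[1]), 0.01)
})

test_that("calibrated baseline satisfies the population and incidence constraints", {
  m <- test_model()
  targets <- derive_population_targets(m$anchors)
  expect_equal(unname(m$baseline$total) / unname(targets), rep(1, 24),
               tolerance = 1e-9)
  expect_equal(unname(m$baseline$total[1]), 215.504, tolerance = 1e-3)
  expect_equal(unname(m$baseline$total[24]), 267.401, tolerance = 1e-3)
  # overall first-year incidence brackets the published average
  expect_gt(m$residuals$first_year_overall_incidence, 0.010)
  expect_lt(m$residuals$first_year_overall_incidence, 0.013)
  # solved base mortality is demographically plausible
  expect_true(all(m$demography$base_death_rate > 0.005 &
                    m$demography$base_death_rate < 0.02))
})

test_that("diagnosed share stays within its band over the horizon", {
  m <- test_model()
  share <- m$baseline$counts[, "DIAG_DM"] /
    rowSums(m$baseline$counts[, dm_states()])
  expect_true(all(abs(share - m$inputs$diagnosed_share_of_dm) <= 0.02))
  expect_lte(m$residuals$diagnosed_share_max_dev, 0.02)
})

test_that("risk-stratum shares of the non-diabetic population are quasi-stationary", {
  m <- test_model()
  nondm <- rowSums(m$baseline$counts[, nondm_states()])
  for (s in c("IFG_ONLY", "IFG_IGT")) {
    share <- m$baseline$counts[, s] / nondm
    expect_true(all(abs(share / share[1] - 1) < 0.10))
  }
})

test_that("doubling the detection rate raises the diagnosed share", {
  m <- test_model()
  run_share <- function(det) {
    p <- update_parameters(m$params, detection_rate = det)
    dem <- m$demography
    dem$base_death_rate <- NA_real_
    r <- project(m$initial, p, dem, end_year = m$end_year)
    mean(r$counts[, "DIAG_DM"] / rowSums(r$counts[, dm_states()]))
  }
  d <- m$params$detection_rate
  expect_gt(run_share(2 * d), run_share(d))
})

test_that("with zero progression the prediabetes pools shrink", {
  m <- test_model()
  p <- update_parameters(m$params, prog_normal_to_ifg = 0,
                         prog_ifg_to_ifgigt = 0)
  r <- project(m$initial, p, m$demography, end_year = m$end_year)
  nondm <- rowSums(r$counts[, nondm_states()])
  expect_true(all(diff(r$counts[, "IFG_IGT"] / nondm) < 0))
  expect_true(all(diff(r$counts[, "IFG_ONLY"] / nondm) < 0))
})

test_that("the combined intervention raises prediabetes prevalence at the horizon", {
  runs <- base_runs()
  prediab <- function(r) {
    n <- length(r$years)
    sum(r$counts[n, c("IFG_ONLY", "IFG_IGT")]) / r$total[n]
  }
  expect_gt(prediab(runs$combined), prediab(runs$none))
})

test_that("calibration is deterministic", {
  m1 <- calibrate_model()
  m2 <- calibrate_model()
  expect_identical(unclass(m1$params), unclass(m2$params))
  expect_identical(m1$demography$base_death_rate,
                   m2$demography$base_death_rate)
})

test_that("the increasing-background trend hits its prevalence-rate target", {
  m <- test_model()
  inc <- calibrate_incidence_growth(m, target_increase_pp = 3.5)
  expect_gt(inc$params$incidence_growth, 1)
  delta <- 100 * (utils::tail(inc$baseline$prevalence_rate, 1) -
                    utils::tail(m$baseline$prevalence_rate, 1))
  expect_equal(unname(delta), 3.5, tolerance = 1e-4)
})
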