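# Base-case run configuration: flat background incidence trend,
# rule-of-halves lifestyle effectiveness, 2% population-wide effectiveness.
parameters:
  lambda_normal: 0.003
  lambda_ifg: 0.024
  lambda_ifgigt: 0.039
  overall_incidence: 0.0122
  rr_undiag: 1.77
  rr_diag: 2.11
  incidence_growth: 1.0

calibration:
  total_dm_rate: 0.129
  ifg_rate_any: 0.267
  ifg_igt_rate: 0.083
  diagnosed_share_of_dm: 0.718
  births_per_year: 4.2
  migration_per_year: 1.0
  anchors:
    years:  [2007, 2010, 2015, 2020, 2025, 2030]
    counts: [27.8, 33.1, 41.2, 48.7, 55.3, 60.7]
    rates:  [0.129, 0.148, 0.175, 0.197, 0.215, 0.227]

horizon:
  start_year: 2007
  end_year: 2030

scenarios: [none, high_risk, moderate_risk, population, combined]

sensitivity:
  targeted: [0.0625, 0.25]
  population: [0.01, 0.04]
  increasing_background: true
  background_rate_increase_pp: 3.5

emulator:
  families: [combined, population, high_risk, moderate_risk]
  targeted_median: 0.125
  population_median: 0.02
  n_samples: 10000
  seed: 1

output:
  directory: glucostate_output
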