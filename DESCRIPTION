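Package: glucostate
Title: Five-State Projection of Adult Diabetes Prevalence Under
    Prevention Policies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time compartmental model that projects the adult
    US diabetes epidemic over a multi-decade horizon by tracking five
    glucose-tolerance states (normal glycaemia, impaired fasting glucose
    with and without impaired glucose tolerance, undiagnosed and diagnosed
    diabetes) through an annual transition matrix with births, migration
    and state-specific mortality.  Includes calibration of the implicit
    rates (detection, diagnosed-at-onset, prediabetes progression, base
    mortality) to published prevalence and population anchors, comparison
    of targeted and population-wide prevention scenarios, one-variable-at-
    a-time sensitivity analysis, a synthetic demography generator for
    testing, and a log-linear run emulator that propagates subjective
    intervention-effectiveness uncertainty into approximate credibility
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
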