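Package: healthspan
Title: Multistate Life Table Estimation of Disability-Free Life Expectancy
    from Interval-Censored Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating age-specific transition probabilities of a
    three-state (non-disabled, disabled, dead) Markov model from
    interval-censored panel data by maximum likelihood, and for turning the
    fitted model into multistate life table quantities: disability-free life
    expectancy, expected duration with disability, and total life expectancy,
    with parametric-bootstrap confidence intervals.  Includes deterministic
    coding rules for social-participation exposure, depression screening and
    non-communicable-disease risk counts, an exclusion cascade with full
    accounting, a synthetic cohort generator that emulates an annual-wave
    disability follow-up of community-dwelling older adults, an independent
    microsimulation cross-check of the life-table math, and a pipeline that
    assembles group-specific and stratified disability-free life expectancy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
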