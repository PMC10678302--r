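Package: gtbudget
Title: Stochastic Budget-Impact Simulation of Gene Therapy Approvals,
    Uptake, and Spending
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of the aggregate financial impact of a
    pipeline of late-stage gene-therapy programs on a healthcare system.
    Combines a disease/trial registry model, correlated program-success
    simulation through a Gaussian copula, trial-duration imputation and
    regulatory timing, steady-state prevalence-incidence conversion,
    exponential depletion of the prevalent patient stock, ramp-shaped market
    penetration, and quality-adjusted-life-year (QALY) anchored launch
    pricing.  Produces monthly patient, spending and QALY series with
    uncertainty bands, annual and payer (Medicare/Medicaid/private)
    decompositions, tornado-style one-way sensitivity analyses, correlation
    and uptake sweeps, and a Poisson pipeline-extension scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
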