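Package: germBO
Title: Bayesian Optimization of Seed Germination Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Closed-loop Bayesian optimization of environmental conditions
    (temperature schedules, water supply) for seed germination trials in
    climatic chambers. Provides a Bernoulli-derived germination score and
    its noise model, Gaussian-process regression with a constant mean and a
    composite amplitude x Matern-5/2 + white-noise kernel fitted by
    multi-start maximum likelihood, upper-confidence-bound acquisition
    maximized under exploitation/exploration distance constraints, batch
    suggestion via predictive-mean fantasy observations, a trial-ledger
    session workflow, and a two-stage Bernoulli germination simulator for
    testing the whole loop without a laboratory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'parameter-space.R'
    'germination-score.R'
    'gp-model.R'
    'acquisition.R'
    'simulator.R'
    'session.R'
    'trial-tables.R'
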