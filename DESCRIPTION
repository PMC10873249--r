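Package: mutorder
Title: Order-of-Mutation Effects in Myeloproliferative Neoplasms
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic models for order-of-mutation
    effects on gene expression and clonal composition in myeloproliferative
    neoplasms (MPN) carrying JAK2 V617F and TET2 mutations.  Implements a
    bistable gene-expression ODE with cubic autoregulation (fixed points,
    saddle-node thresholds, hysteretic branch-following over mutation
    histories, coupled two-gene variant) and a generalized five-type Moran
    birth-death-mutation process (exact one-step kernel, Monte-Carlo
    simulation, exact transient probability propagation to the first
    double-mutant, conditional first-passage statistics, system-size sweeps
    and t-test sample-size estimates).  Scenario presets reproduce the
    published steady-state expression tables and conditional absorption
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
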