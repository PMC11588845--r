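Package: bindmem
Title: Hierarchical Bayesian Measurement Models of Binding and Item
    Memory in Serial Reconstruction Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring and Bayesian measurement modelling of
    8-alternative serial reconstruction data from working-memory span
    tasks.  Trials present four words that are later reconstructed, in
    order, from a grid of the four targets plus four never-presented
    lures.  Responses are categorized as Correct, Other or New and
    modelled with two hierarchical Bayesian measurement models that
    separate binding memory (an item tied to its serial position) from
    item memory: a discrete-state multinomial processing tree and a
    continuous activation model in which choice follows normalized
    activations (Luce's rule).  The package provides free and serial
    scoring, preregistered-style exclusion filtering, posterior
    condition contrasts with 95% equal-tailed credibility intervals,
    posterior-predictive simulation, convergence diagnostics, a
    synthetic-data generator emulating span-task experiments, and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
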