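Package: ctrlbridge
Title: Stochastic Control Costs of Brain State Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the optimal control cost of transitions between Gaussian
    brain states under linear stochastic (Ornstein-Uhlenbeck) dynamics. Solves
    the Gaussian Schroedinger bridge between an initial and a target state
    distribution, decomposes the minimal cost into mean and covariance control
    components, and attributes the expected squared control input to individual
    network nodes (regions of interest). Includes a time-series estimation
    pipeline (trace normalization, sparse VAR(1) fit, continuous-time
    conversion), seeded synthetic-data generators that double as Monte-Carlo
    oracles, and a bootstrap analysis pipeline producing cost tables, input
    maps, entropy and coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
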