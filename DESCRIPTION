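Package: hospfrontier
Title: Panel Stochastic Frontier Analysis of Hospital Technical Efficiency
    and Fiscal Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates hospital technical efficiency from an unbalanced
    hospital-year panel by maximum likelihood under the normal-truncated-normal
    composed-error stochastic frontier model with time-invariant inefficiency
    (Battese-Coelli random effects).  Supports Cobb-Douglas, translog and
    multi-output distance functional forms, Battese-Coelli conditional-mean
    efficiency scores, likelihood-ratio selection between nested forms,
    output elasticities with returns-to-scale classification, and conversion
    of efficiency gaps into potential budgetary savings (fiscal space).
    Includes a synthetic-panel generator with known ground truth emulating a
    small national hospital system, so the whole pipeline is testable without
    confidential hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
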