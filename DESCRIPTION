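Package: orphanval
Title: Risk-Adjusted Valuation of Rare-Disease Drug Development Portfolios
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A valuation toolkit for early-stage rare-disease drug
    compounds developed through abbreviated regulatory pathways. Provides a
    deterministic risk-adjusted net present value (rNPV) engine over a
    configurable clinical-phase plan and commercial model, a multi-stage
    Monte Carlo simulator with PERT-distributed costs and durations,
    confidence-interval-calibrated price and adoption assumptions and
    Gaussian-copula dependence, and a portfolio simulator that quantifies
    the diversification benefit of developing several pairwise-correlated
    compounds. Scenario assumptions are read from and written to plain
    YAML/JSON files; results export as JSON reports and CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
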