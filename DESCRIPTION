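Package: saltreg
Title: Robust Quadratic Regression Modelling of Rice Salinity-Tolerance Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling shoot biomass of salt-grown rice from
    high-throughput phenotyping traits (SPAD chlorophyll index, stomatal
    conductance, shoot sap Na+ and K+). Implements a full quadratic
    response-surface model fitted by singular value decomposition with
    truncated singular values, heteroskedasticity-consistent (HC3) slope
    covariances, leave-one-out (predicted) residuals and holdout performance
    measures, a three-phase stepwise search for the largest all-significant
    term set, cyclic outlier screening with Benjamini-Hochberg false-discovery
    control on externally studentized residuals, heteroskedasticity and
    Monte-Carlo Jarque-Bera normality diagnostics, and a prediction engine
    producing response-surface scenario tables with t-based confidence bands.
    A synthetic phenotype generator with known ground truth supports
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
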