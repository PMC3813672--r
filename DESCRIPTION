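Package: soilKpath
Title: Path-Coefficient Analysis of Soil Potassium Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the status and transformation of soil
    potassium pools (water-soluble, exchangeable and non-exchangeable K)
    from tabular soil-property surveys. Computes molar-oxide weathering
    indices (CIA, saf, ba, Na/K), builds significance-flagged Pearson
    correlation surfaces, fits standardized multiple regressions with
    backward elimination and decomposes each response-predictor
    correlation into Wright path coefficients (direct, indirect and
    residual effects), and classifies the direction of the
    wsK/eK/neK equilibrium shift via calibrated contribution-coefficient
    functions. Includes a multivariate-normal synthetic-data generator
    with known structural coefficients so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
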