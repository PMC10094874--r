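Package: tbakit
Title: Total Bioactivity Accounting for Bioactivity-Guided Purification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative bookkeeping of bioactivity through natural-product
    purification campaigns. Converts half-maximal inhibitory concentrations
    (IC50/EC50) to half-maximal effective dilution volumes (EDV50 = 1/EC50,
    in L/g), computes the total bioactivity (TBA = EDV50 x solid weight) of
    extracts, chromatographic fractions and purified compounds, normalizes
    bioactivity per gram of dry starting material, and balances mass and
    bioactivity recovery across purification steps to distinguish additive
    from synergistic or antagonistic behaviour. Includes a four-parameter
    logistic dose-response fitter for serial-dilution inhibition data, a
    ground-truth simulator of mixtures and fractionation campaigns under
    Loewe-style dose additivity, CSV/JSON readers and writers for campaign
    tables and purification trees, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
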