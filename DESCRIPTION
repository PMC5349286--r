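Package: rumenh2
Title: Metabolic Hydrogen Balance Accounting for Rumen Fermentation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts fermentation end-product concentrations and gas data
    from semi-continuous rumen fermenter (RUSITEC) experiments into daily
    molar fluxes and applies reaction stoichiometries to account for
    metabolic hydrogen ([2H]) produced, consumed, balanced and recovered
    under alternative caproate-origin scenarios. Includes CO2-equivalent
    greenhouse-gas aggregation, nitrate and microbial-biomass electron-sink
    estimates, dissolved-hydrogen supersaturation factors, descriptive
    fermentation summaries, and a synthetic vessel-by-day data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
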