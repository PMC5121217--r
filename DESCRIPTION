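Package: chainelongr
Title: COD Accounting, Membrane Pertraction Modelling, and Microbiome
    Correlation for Chain-Elongation Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for anaerobic chain-elongation bioreactors that
    convert ethanol-rich organic residues (such as wine lees) into medium-chain
    carboxylates (n-caproate, n-caprylate) with in-line membrane-based
    liquid-liquid extraction (pertraction).  Provides chemical-oxygen-demand
    (COD) bookkeeping from elemental composition, period-level mass balances
    (extraction, washout, production, productivity, yield, specificity),
    an overall mass-transfer coefficient model linear in the broth-recycle
    superficial velocity with cross-study flux prediction, operational-
    taxonomic-unit (OTU) abundance versus productivity correlation analysis
    with Bray-Curtis/UPGMA ordering and principal coordinates analysis, and a
    synthetic-data generator with planted parameters for end-to-end pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
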