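Package: fluxlogic
Title: Coupling Boolean Regulatory Models with Constraint-Based Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Boolean regulatory networks from CellDesigner
    process-description molecular interaction maps, computes their minimal
    trap spaces via a prime-implicant constraint encoding, translates
    components proven asymptotically inactive into zero-flux constraints on
    a constraint-based metabolic model, and compares control versus
    contextualized flux balance / flux variability analyses through
    glycolytic and oxidative ATP-production ratios. Includes readers and
    writers for the BNET, SBML-qual, SBML-fbc and CellDesigner XML formats,
    a synthetic generator of coupled regulatory/metabolic toy models, and a
    command-line pipeline reproducing the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
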