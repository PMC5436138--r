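Package: importomics
Title: Organellar Importome Analysis from Knockdown Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for defining organellar importomes from
    quantitative knockdown proteomics. Reads replicate-level heavy/light
    ratio tables (MaxQuant proteinGroups dialect), orients label-switched
    replicates, applies identification and quantification filters,
    summarises per-protein log2 ratios with one-sample t-tests, derives
    depletion thresholds by a dual-reference F1-score scan, calls imported
    versus unaffected proteins, flags new organellar candidates, predicts
    MIA-pathway substrates by twin Cx3C/Cx9C motif scanning with a
    molecular-mass gate, and tests term or substrate overrepresentation
    with two-sided Fisher's exact tests and Benjamini-Hochberg correction.
    A synthetic-data generator with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
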