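Package: ratiomap
Title: Ratiometric Proximity-Labeling Proteomics and Organelle Contact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric proximity-biotinylation
    proteomics of open cellular compartments. Reads MaxQuant-style protein
    group tables, normalizes three-state SILAC ratios to a soluble reference
    subset, selects log2 ratio cutoffs by maximizing the difference between
    true- and false-positive rates over curated protein lists, intersects
    replicates into final spatial proteomes, and scores specificity,
    coverage and orphan membership against annotation catalogs. Also
    implements moderated one-sample t-tests with empirical-Bayes variance
    shrinkage and Benjamini-Hochberg FDR control for isobaric-tag (iTRAQ)
    immunoprecipitation enrichment calling, and quantifies
    mitochondria-endoplasmic-reticulum contact sites from traced electron
    microscopy contours as perimeter fractions within a distance threshold.
    Seeded synthetic-data generators with known ground truth make every
    stage testable without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
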