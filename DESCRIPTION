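Package: trajmet
Title: Trajectory Metabolomics and 13C Tracer Analysis for Three-Group
    Tumorigenesis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for GC-MS metabolomics and transcriptomics of
    staged tumorigenesis models with three tissue groups (normal, precancerous,
    tumor). Provides interquartile-range peak denoising, internal-standard
    normalization, pairwise differential calling with fold-change reports,
    a trajectory expression-pattern classifier that assigns analytes to
    tumor-associated and oncogene-associated categories, PCA and PLS-DA with
    VIP scores and permutation validation, hypergeometric pathway
    over-representation analysis with a built-in central-carbon pathway map,
    and a steady-state atom-mapped simulator of [U-13C]glucose isotopologue
    distributions through glycolysis, the pentose phosphate pathway, the TCA
    cycle and the citrate-malate shuttle, validated against a molecule-level
    Monte-Carlo oracle. A synthetic-data generator with planted ground truth
    makes every stage testable without raw instrument data.
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
    withr,
    mixOmics,
    fgsea,
    yaml
Config/testthat/edition: 3
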