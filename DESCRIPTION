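Package: fecanet
Title: Variability Decomposition and Partial-Correlation Networks for
    Fecal Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and statistical analysis of untargeted fecal
    metabolomics and lipidomics peak tables: internal-standard
    normalization, pooled-QC relative-standard-deviation filtering,
    k-nearest-neighbor imputation, three-level coefficient-of-variation
    decomposition (technical, drill-area, participant), feature-wise
    moderated F-tests with Benjamini-Hochberg correction, cross-platform
    compound-category integration, and sparse partial-correlation
    networks estimated with the graphical LASSO under a rotation-based
    penalty criterion. Includes a synthetic-study generator that emulates
    a replicate sampling design (participants by cryogenic drill areas
    plus pooled quality-control injections) with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
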