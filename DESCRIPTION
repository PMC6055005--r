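Package: tfclust
Title: Spectral Clustering and Functional Enrichment of Transcription
    Factor Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns putative functions to uncharacterized (hypothetical)
    bacterial transcription factors from an expression compendium.
    Implements the full workflow: imputation and principal-component
    analysis of a TF-by-condition log-ratio matrix, selection of
    informative conditions by a projection-threshold plus
    correlation-block rule, spectral clustering of TFs on a k-nearest-
    neighbour similarity graph with selectable graph Laplacian, selection
    of the number of clusters by within-sum-of-squares descent, stability
    assessment over random restarts, and characterization of clusters by
    one-tailed Fisher exact enrichment of TF families, regulatory modes
    and target-gene functional categories with Benjamini-Hochberg
    correction. Includes a synthetic-data generator with planted cluster
    structure and planted category enrichments so every stage can be
    validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
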