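Package: biosystax
Title: Integrative Biosystematics from Dominant Markers, Karyotypes,
    Phytochemistry and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative biosystematic analysis of closely related
    plant taxa, built around the evidence streams used in revisions of genera
    such as Datura: dominant-marker band matrices (ISSR, SCoT, CDDP) with
    polymorphism and PIC statistics and binary similarity coefficients;
    distance-based tree inference (neighbor-joining and UPGMA) with cophenetic
    and Mantel concordance tests; karyotype morphometrics with Levan centromere
    classification and Romero Zarco asymmetry indices; calibration-based
    phytochemical quantification and chemometric PCA/HCA; relative gene
    expression by the 2^(-ddCt) method; and a weighted multi-evidence consensus
    that yields pairwise similarity percentages and a configurable
    taxonomic-rank suggestion. A synthetic-data module generates every input
    with known ground-truth structure so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
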