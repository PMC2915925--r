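Package: peroxiscreen
Title: Quantitative Phenotyping for a Genome-Wide Peroxisome Biogenesis Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a high-content screen of peroxisome
    biogenesis in budding yeast using a GFP-tagged matrix-protein reporter.
    Provides synthetic-data generators with known ground truth (flow-cytometry
    event tables, 3D confocal stacks of budded cells, multi-study hit
    catalogs), flow-cytometry scoring (scatter regression correction, quantile
    normalization, z-scores and threshold hit calling), 3D puncta segmentation
    and volumetry (cell segmentation, low-pass filtering, per-slice
    thresholding, slice recombination into 3D objects), strain phenotype
    classification (mislocalization, inheritance defects, size and clustering
    phenotypes), and multi-study regulator integration with hypergeometric
    gene-set enrichment and network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    jsonlite,
    limma,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
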