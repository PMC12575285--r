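Package: karstpatch
Title: Patch-Scale Biodiversity Analysis for Fragmented Karst Soils
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for patch-scale analysis of plant diversity in rocky,
    fragmented landscapes such as karst abandoned farmland. Delineates soil
    patches from gridded soil-depth rasters and computes patch geometry
    (area, perimeter, fractal dimension), soil resource availability and
    heterogeneity (means and coefficients of variation), taxonomic diversity
    (richness, Shannon-Wiener, Pielou evenness), Faith's phylogenetic
    diversity, and phylogenetic community structure (NRI and NTI) under a
    seeded tip-shuffle null model. Includes a synthetic-data generator that
    emulates the sampling design so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
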