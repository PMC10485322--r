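Package: dietniche
Title: Dietary Niche Breadth and Overlap from DNA Metabarcoding Incidence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-classification analysis of DNA metabarcoding diet surveys
    based on presence/absence (incidence) of prey OTUs in pooled fecal
    samples. Reads and validates OTU tables with taxonomy lineage strings,
    applies phylum, host-exclusion and classifier-confidence filters,
    collapses incidence to a chosen taxonomic rank, and computes standard
    ecological niche statistics: Levins and Shannon-Wiener niche breadth
    with their standardized forms, MacArthur-Levins directional overlap,
    Pianka symmetric overlap, exclusive-subset (Venn) resource counts, and
    Monte-Carlo chi-square tests of dietary composition under a
    fixed-margin contingency-table null. Includes a synthetic incidence
    generator with exact control of per-group richness and pairwise
    sharing so every pipeline stage can be tested without raw sequence
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
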