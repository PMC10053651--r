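Package: centrohor
Title: Hierarchical Annotation of Centromeric Higher-Order Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic structure annotation of centromeric satellite DNA
    arrays. An array is decomposed into monomer-sized blocks by dynamic
    programming against a monomer template, monomers are inferred by Louvain
    community detection on a block similarity graph over a schedule of
    similarity thresholds, and higher-order repeats (HORs) -- including
    local-nested HORs in which a sub-span of consecutive monomers is itself
    tandemly amplified -- are mined by hierarchical tandem repeat mining with
    bottom-up repeat compression. HORs are merged across unit rotations,
    scored by coverage and nesting degree, ranked and named, and projected to
    genomic coordinates. Includes a satellite-array simulator with ground
    truth for benchmarking and a bin-based positional enrichment test for HOR
    pattern classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
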