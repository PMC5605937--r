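Package: phagesite
Title: Detection of Phage Integration Sites from Junction-Enriched Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for calling bacteriophage
    integration sites in a bacterial host genome from junction-enriched
    paired-end sequencing libraries. Read 1 of each pair carries a constant
    phage anchor followed by the 7-nt strand-exchange overlap and host flank;
    the package filters and trims reads, maps the host remnants with a
    seed-and-extend mapper under a 95 percent identity contract, collapses
    junctions into an integration-site catalog with replicate detection
    frequencies and the secondary-to-attB read ratio, builds a 29-base
    position-specific scoring matrix around the sites, scans the genome for
    the motif-score background, and vets CRISPR-Cas9 sgRNA candidates that
    select for lysogens at a chosen site. A synthetic-library simulator with
    a ground-truth manifest makes every stage verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    S4Vectors,
    graphics,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
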