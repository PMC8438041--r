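Package: asvirome
Title: Virome Screening, CRISPR-Based Host Prediction and Ecology for
    Activated Sludge Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reimplements an activated-sludge virome analysis workflow on
    synthetic communities with planted ground truth: identification of viral
    contigs from gene-annotation hit tables (viral-protein-family screening
    plus an LCA taxonomic route), genus-level clustering of viral contigs by
    shared protein-cluster content, detection of CRISPR repeat-spacer arrays
    in host genomes, spacer-to-protospacer matching for virus-host
    prediction with precision/recall benchmarking and a random-sequence
    null, coverage-based abundance and diversity analysis (Shannon, Pielou,
    Bray-Curtis ordination, rarefaction, core genera), and Hi-C contact
    deconvolution with CRISPR cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
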