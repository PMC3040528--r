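Package: varkv
Title: Desk-Scale Column-Family Key-Value Query Engine for Genomic Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embedded, byte-ordered key-value store for genomic variation
    data, modelled on BigTable-style column-family schemas: rows are keyed by
    genomic start position, four column families hold variants, per-base
    coverage blocks, features and coding consequences, per-genome column
    labels hold many genomes in one table, and cell versions distinguish
    co-located variants. Includes SAMtools (classic) pileup, BED, GFF and
    key-value loaders with a plugin registry, a tag-based secondary index, a
    query layer with field and tag filters, BED and WIG (per-base and
    block-averaged) export, a map-reduce-style traversal framework with
    variant-type counting and tumor/normal somatic subtraction, a stateless
    HTTP query service, and a deterministic synthetic-data generator with
    machine-readable truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
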