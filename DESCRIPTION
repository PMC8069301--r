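Package: nicd
Title: Network-Based Identification of Common Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate driver genes shared by two diseases from a
    gene-gene interaction network and DisGeNET-style variant-disease and
    variant-gene mapping tables. Genes with direct network links to both
    disease gene sets are collected as primary candidates, assessed against
    a permutation null with Benjamini-Hochberg false discovery rate control,
    and annotated by Fisher-exact pathway enrichment over GMT libraries.
    Includes a synthetic-scenario generator with planted drivers and
    one-sided decoys for end-to-end validation, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
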