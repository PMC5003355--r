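Package: procoexp
Title: Weighted Protein Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted co-expression network analysis for small label-free
    proteomics experiments. Builds soft-thresholded correlation networks
    from arcsinh-transformed intensity matrices, selects the soft power by
    scale-free topology fit, detects modules from the topological overlap
    matrix, correlates module eigengenes with sample traits, calibrates
    correlation cutoffs by permutation false-discovery estimation, extracts
    dense clusters (MCODE), hub proteins and Ward sub-clusters, compares
    co-expression networks against reference interaction networks (Jaccard,
    hypergeometric and Erdos-Renyi randomisation statistics), performs
    hypergeometric term enrichment, and ships a synthetic-data generator
    with planted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
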