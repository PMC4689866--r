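Package: mybcoexp
Title: Co-Expression Network Modules and Guide-Gene Target Nomination for
    MYB Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signed Pearson co-expression networks from log2
    expression matrices, selects a correlation cutoff by topology
    diagnostics (density, scale-free fit), detects modules with a
    from-scratch Markov Clustering implementation tuned by an inflation
    sweep scored with a GO-enrichment F-measure, and calls degree-based
    hub genes. A second, guide-gene workflow expands a network outward
    from seed transcription factors by mutual rank and correlation
    thresholds, scans 1 kb promoters for MYB-binding cis-elements on both
    strands, and nominates putative target genes. Ships a synthetic-data
    generator with planted co-expression modules, differential expression,
    module-aligned annotation terms, and promoter motifs at known
    positions, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
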