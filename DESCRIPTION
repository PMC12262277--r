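Package: spathet
Title: Spatial Heterogeneity Analysis for Multiplexed Tissue Imaging and
    Microregional Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoral heterogeneity in multiplexed
    immunofluorescence and microregional transcriptomic data from tissue
    sections. Provides gate-based single-cell phenotyping and tumor-state
    calling, Delaunay-graph local Shannon entropy and a region-level spatial
    entropy statistic, recurrent cellular neighborhood (RCN) clustering with
    meta-grouping, epidermis-referenced invasion bands, comparative proximity
    analysis around focal tumor states, self-organizing-map metagene portraits
    with overexpression cluster areas, and a Pearson correlation spanning tree
    over microregions with branch decomposition. Includes a marked
    point-process tissue simulator and a negative-binomial expression
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    deldir,
    igraph,
    jsonlite,
    limma,
    Matrix,
    sp,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
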