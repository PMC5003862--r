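Package: hubgenes
Title: Imaging Transcriptomics of Brain Network Hubs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Relates nodal topology of functional brain networks to regional
    gene expression. From regional BOLD time series the package computes
    wavelet (MODWT, Daubechies-4) correlation matrices, builds minimum
    spanning tree anchored binary graphs at target connection densities,
    finds a consensus Louvain modular partition at resolution gamma, and
    derives nodal metrics (intra-/inter-modular degree, participation
    coefficient, mean connection distance). Partial least squares (PLS2,
    NIPALS) relates the nodal metrics to whole-genome expression, with
    bootstrap gene ranking, naive and spatially blocked permutation
    inference, minimum-hypergeometric ranked-list enrichment against GMT
    annotations, and candidate-gene-set permutation tests. A synthetic-data
    generator plants spatially embedded modular networks and low-rank
    expression components with recoverable ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
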