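Package: snapkit
Title: Depth-Corrected Spectral Embedding and Clustering of Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A peak-free toolkit for single-cell ATAC-seq. Builds binary
    cell-by-bin matrices from fragment files, removes the sequencing-depth
    confounder from the pairwise Jaccard kernel by regressing observed on
    expected Jaccard similarity, and computes a symmetric-normalized spectral
    embedding. Scales to large datasets through landmark (Nystrom) extension
    and an ensemble of landmark samplings combined as a weighted KNN graph.
    Downstream machinery includes graph-based clustering with evaluation
    metrics, diffusion-smoothed gene accessibility scores, projection of query
    cells onto a reference embedding with mutual-nearest-neighbor label
    transfer, enhancer-gene association by logistic regression with
    distance-matched negative controls, and differential accessibility testing
    with a fixed-dispersion negative-binomial exact test. A synthetic-data
    module generates ground-truth datasets for benchmarking every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
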