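Package: jembed
Title: Joint t-SNE and UMAP Embeddings of Multimodal Single-Cell Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generalizes t-SNE and UMAP to the joint visualization of
    single-cell multimodal omics data (e.g. CITE-seq RNA plus ADT counts).
    Cells measured in several modalities are embedded into a single
    low-dimensional map by minimizing an entropy-regularized convex
    combination of per-modality Kullback-Leibler divergences (j-SNE) or
    fuzzy cross entropies (j-UMAP), learning per-modality importance
    weights on the probability simplex by an alternating optimization
    scheme. Ships evaluation metrics (k-nearest-neighbor index,
    silhouette, adjusted Rand index), concatenation and fixed-weight
    baselines, a Splatter-style multimodal count simulator with a
    shuffled-noise modality, and file-based command line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    cluster,
    mclust,
    minpack.lm,
    jsonlite,
    data.table,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
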