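Package: spview
Title: Multi-View Graph Contrastive Learning for Spatial Domain Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies spatial domains in spatially resolved transcriptomics
    (SRT) data from one or several tissue slices. Spot embeddings are learned
    by a two-view graph convolutional autoencoder: one view encodes spatial
    proximity, the other expression similarity, and the two are fused by a
    per-spot attention block. Training combines a reconstruction loss with an
    instance-level and a cluster-level contrastive loss; multi-slice data are
    integrated through learnable per-slice prompt embeddings that absorb batch
    effects. Domains are called by Gaussian-mixture clustering of the fused
    embeddings followed by a spatial majority-vote refinement, and the package
    ships external/internal clustering metrics plus a synthetic multi-slice
    SRT generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
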