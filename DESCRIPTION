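Package: polpause
Title: Profiling RNA Polymerase II Pausing Downstream of Gene 3' Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strand-aware tag-density profiling of RNA polymerase II
    ChIP-seq occupancy around the end of annotated genes (EAGs):
    isolated-gene filtering, directional read extension and binned
    coverage, orientation-normalised anchor matrices, K-means clustering
    of 3' pause patterns, pause-extent and exponential decay-length
    estimation, expression stratification, sense/antisense nascent-read
    fractions, and a two-condition perturbation comparison of
    mock-normalised region signals. Includes a parametric synthetic read
    generator with planted narrow (core-histone-like) and broad
    (poly(A)+-like) pause shapes that serves as ground truth for the
    whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
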