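Package: spikeMADS
Title: RT-qPCR Profiling and Co-Expression Set Assignment for MADS-Box
    Genes in Cereal Spike Development
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relative quantification of RT-qPCR assays across a
    developmental time course, with geNorm-style reference-gene stability
    scoring, delta-Cq normalization against the best-matching reference
    panel, and correction of assays covered by an overlapping antisense
    transcript. Normalized profiles are grouped into co-expression sets by
    a Pearson threshold-graph rule (the m-core of the r > tau graph), with
    a looser pseudoset and a hierarchical-clustering cross-check, and
    floral-organ expression is scored against ABCDE-model expectations.
    A synthetic-data generator emulating a barley inflorescence time
    course (Waddington stages W1-W10.5) with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, Clustering, Network, Software
RoxygenNote: 7.3.3
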