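Package: cisClust
Title: Intra-Chromosomal Co-Expression Clustering with a Random-Matrix Null
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyzes the full intra-chromosomal (cis-) gene co-expression
    landscape of expression cohorts. Builds per-chromosome Pearson correlation
    matrices, calibrates them against an ensemble of correlation matrices of
    within-sample shuffled data (whose spectrum follows the Marchenko-Pastur
    law), selects the number of gene clusters as the count of eigenvalues
    deviating from that null, clusters genes by k-medoids (PAM) on the
    1 - |correlation| dissimilarity, and quantifies the spatial organization
    of the resulting clusters along the chromosome via nearest-neighbor
    distance distributions, Shannon entropy, and Kolmogorov-Smirnov distances.
    Includes correlation-versus-genomic-distance profiles with a piece-wise
    Kolmogorov-Smirnov comparison against the shuffled null, and a synthetic
    expression generator with planted correlation structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
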