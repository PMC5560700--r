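Package: brnet
Title: Bayesian Relevance Networks for Grouped Sequencing Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds co-expression (relevance) networks from entity-by-sample
    read-count matrices in which samples are organized into groups, such as
    cancer types or replicate sets. Expression fractions are estimated under a
    Dirichlet-multinomial posterior so that finite sequencing depth translates
    into explicit uncertainty; grouped correlations are then moderated by that
    uncertainty through the laws of total variance and covariance, suppressing
    spurious correlations driven by a handful of reads. Includes the classical
    grouped Pearson baseline on reads-per-million, optional entropy filtering
    of low-complexity expression profiles, permutation-based null
    distributions with false-discovery-rate estimates, network construction
    and comparison with genomic-locality annotation of edges, and a
    multinomial simulator with planted co-expression modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
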