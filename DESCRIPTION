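Package: coevocomm
Title: Parallel Evolution and Community Transcriptome Analysis for
    Predator-Prey Coevolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for microbial coevolution experiments that
    track replicate evolved populations and multi-species community
    transcriptomes. Implements nucleotide and gene multiplicity statistics
    for detecting parallel molecular evolution against uniform null models
    with an empirical-null critical-p false discovery rate procedure;
    species-resolved differential expression with within-taxon sum scaling,
    negative binomial generalized linear models with a taxon relative
    abundance covariate, heavy-tailed prior log fold change shrinkage, a
    regularized log transform, and hypergeometric pathway enrichment; and
    DiSTATIS compromise analysis of multi-table expression distances with
    bootstrap prediction ellipses, k-means cluster number selection by the
    Krzanowski-Lai index, and permutational MANOVA and dispersion tests.
    A synthetic data module generates variant tables, gene catalogs and
    multi-taxon count matrices with the assumed statistical structure so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
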