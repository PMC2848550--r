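Package: rtcscore
Title: Regulatory Trait Concordance Scoring of eQTL-GWAS Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decides whether a GWAS SNP and a colocalizing expression QTL
    in the same recombination-hotspot interval tag the same functional
    variant. Implements the Regulatory Trait Concordance (RTC) score from
    a per-interval residual-correction sweep, together with Spearman
    rank-correlation eQTL mapping with permutation thresholds, pairwise
    linkage-disequilibrium metrics (r-squared and D-prime, phased or via
    EM on unphased genotypes), MAF-matched QQ enrichment curves with
    confidence bands, an immunity-stratified Fisher enrichment test, and
    an LD-structured founder-mosaic simulator for benchmarking the score
    under single- and two-causal-variant scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
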