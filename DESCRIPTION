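Package: cernet
Title: Competing Endogenous RNA Network Inference from Two-Group RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA) regulatory
    networks from small two-group RNA-seq designs. Provides FPKM and tags-per-million
    normalization, a two-group differential expression screen with fold-change and
    p-value thresholds, lncRNA target prediction by antisense overlap, genomic
    proximity (cis) and co-expression (trans) strategies, seed-match miRNA target
    prediction with a two-predictor intersection rule, and the core triplet caller:
    a Spearman anti-correlation screen for miRNA-ceRNA edges, a Pearson screen for
    lncRNA-mRNA pairs, and an upper-tail hypergeometric test on shared miRNA
    regulators. Includes hypergeometric over-representation analysis against GMT
    gene sets, Livak 2^-ddCt relative-expression arithmetic, and a negative-binomial
    synthetic-data generator with planted differential expression and planted ceRNA
    triplets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    fgsea,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
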