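Package: oncomap
Title: Comparative Oncogenomic Analysis of Canine Mammary Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for cohort-level comparative
    oncogenomics of canine mammary tumors (CMTs) and, by projection, human
    breast cancer. Implements somatic-variant post-filtering (alignment-score
    based error removal, consequence classification, recurrence tables,
    germline candidate filtering), tumor mutational burden with purity
    adjustment and a context-corrected dN/dS selection surrogate,
    96-channel trinucleotide mutational-signature analysis (de novo NMF
    deconvolution, catalog matching, non-negative least-squares exposure
    fitting), GC-corrected read-depth copy-number profiles with circular
    binary segmentation and permutation-based recurrence peaks, UCSC-chain
    cross-species projection of copy-number profiles, consensus-NMF
    expression subtyping with cophenetic rank selection and survival
    analysis, and the cohort statistics used throughout (exact Fisher,
    Mann-Whitney U, log-rank, ANOVA, BH-FDR, pathway enrichment). A
    synthetic-cohort module generates every input with planted ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    survival,
    pracma,
    fgsea,
    vcfR,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite
Config/testthat/edition: 3
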