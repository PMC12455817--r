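Package: speqtl
Title: Single-Parent Expression Complementation, Heterosis Variance
    Decomposition and eQTL Mapping in Backcross Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-parent expression (SPE) complementation
    in recombinant-inbred-line (RIL) backcross hybrids. Classifies RIL
    genomes into parental mosaics from SNP genotype calls, normalizes
    RNA-seq counts and calls per-genotype gene activity, assigns SPE
    complementation patterns, decomposes phenotypic heterosis variance
    into a fraction explained by SPE-gene counts (p_Het) with REML mixed
    models, maps expression QTL by Haley-Knott regression on hidden-Markov
    genotype probabilities with permutation thresholds, classifies eQTL as
    cis- or trans-regulating, and associates expression with phenotypic
    traits. Includes a ground-truthed synthetic-cross generator so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
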