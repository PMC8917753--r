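Package: omicblup
Title: Multi-Omic Genomic Prediction with Weighted Relationship Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits in small inbred panels
    from heterogeneous omic layers (sequence variants, expression
    presence/absence variation, gene- and transcript-level expression,
    metabolites). Builds standardized additive relationship kernels per layer,
    fits GBLUP by spectral REML under replicated five-fold cross-validation,
    searches a simplex lattice of kernel weights for the best joined weighted
    relationship matrix, quantifies dataset dissimilarity by generalized
    Procrustes analysis and principal coordinates analysis, and emulates 3'end
    mRNA sequencing by windowing gene models. A synthetic-data generator with
    known genetic architecture provides a ground-truth test surface, including
    adjusted entry means and entry-mean heritability estimated by REML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
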