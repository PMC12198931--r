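Package: triogen
Title: Direct and Indirect Genetic Effects in Parent-Offspring Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-family partitioning of direct (child) and indirect
    (maternal and paternal) genetic effects on child outcomes from genotyped
    parent-offspring trios. Provides a trio genotype and phenotype simulator
    with Mendelian transmission, genomic relatedness matrix (GRM)
    construction with trio block extraction and relatedness-based pruning,
    restricted maximum likelihood (REML) estimation of nested trio
    variance-component models with information criteria and likelihood-ratio
    tests under false-discovery-rate control, questionnaire scale scoring and
    transformation utilities, polygenic score computation with
    residualization, and trio polygenic-score regression with cluster-robust
    sandwich inference and partial r-squared decomposition into direct and
    indirect contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
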