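Package: morphodyn
Title: Multivariate Microglial Morphology Dynamics and Cytokine Network
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how microglial morphology and CNS
    cytokine networks respond to, and recover from, an inflammatory
    stimulus. Provides a seed-reproducible generator of per-cell
    morphometry and qPCR datasets with planted cell states and
    genotype-specific recovery kinetics; expansion of distributed
    per-process measurements into a cells-by-features matrix of
    distribution statistics; spline-based time-course testing of
    genotype differences with a bootstrap null (optimal discovery
    procedure style F statistics); offset non-negative matrix
    factorization with SVD-based initialization for morphological
    cell-state discovery, plus nonmetric multidimensional scaling on
    Spearman rank distances for validation; an adaptation-index
    framework with closed-form error propagation and eligibility rules
    for genotype comparisons; and a two-compartment ordinary
    differential equation model of microglia-environment cytokine
    signaling with Hill kinetics, knockout simulation, and
    dose-response adaptation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    deSolve,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    mclust,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
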