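Package: mindwandr
Title: Simulation and Analysis of Mind Wandering, Metacognition and
    Cognitive Control Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts performing a Go/No-Go sustained-attention
    task with thought probes, a two-alternative dot-discrimination task
    with confidence ratings under a weighted up-down staircase, and an
    arrow-priming conflict task, from per-subject latent traits drawn
    through a Gaussian copula. Analyses compute behavioral mind-wandering
    indicators and their latent factor, a subjective mind-wandering
    detection index, signal-detection metacognitive efficiency
    (meta-d'/d' by maximum likelihood), congruency-sequence (Gratton)
    indices with repeated-measures ANOVA, robust multivariate outlier
    flags, and a maximum-likelihood path model with sandwich standard
    errors and chi-square/CFI/RMSEA fit indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
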