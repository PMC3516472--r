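Package: mutacc
Title: Analysis of Mutation-Accumulation Fitness Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation pipeline for mutation-accumulation (MA) fitness
    experiments with a nested line/subline/replicate design: demographic
    relative fitness from day-structured reproduction schedules (Euler-Lotka
    solve for the control intrinsic rate of increase), among-subline and
    residual variance components (method of moments and REML), per-generation
    mutational decay of mean fitness and mutational variance, mutational
    heritability, Bateman-Mukai estimates of the genomic mutation rate and
    mean mutational effect with subline-level bootstrap confidence intervals,
    and a calibrated synthetic MA-experiment generator for validation and
    power analysis.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmmTMB,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
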