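Package: soygs
Title: Genomic Selection Analysis for Soybean Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating genomic selection in an applied inbred-line
    breeding program: RR-BLUP marker-effect and kinship GBLUP prediction of
    yield and seed-composition traits, genomic heritability via spectral REML
    on an additive relationship matrix, multi-environment phenotypic BLUPs
    from an all-random-effects model fitted by EM-REML on Henderson's mixed
    model equations, three cross-validation designs (whole-dataset,
    within-family, across-family with full-sib exclusion) over training-set
    size and marker-density sweeps, LD-based greedy tag-SNP selection and
    thinning, principal-component structure diagnostics with a
    population-mean inflation decomposition, and ANOVA with Fisher's LSD
    grouping of replicate predictive abilities. Includes a bi-parental
    recombinant-inbred-line simulator (single-seed descent under a Haldane
    map) so the whole analysis is testable end to end without external data.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
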