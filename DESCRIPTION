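Package: pgsmed
Title: Polygenic Scoring and Causal Mediation for Adolescent Disordered Eating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline linking a body-mass-index polygenic
    score to disordered-eating outcomes in an adolescent cohort: harmonization
    of discovery GWAS summary statistics with target genotypes, LD clumping and
    p-value-threshold-optimized polygenic scoring, Nagelkerke pseudo-R2 with
    liability-scale conversion and permutation empirical p-values,
    covariate-adjusted association and random-intercept longitudinal models,
    and counterfactual causal mediation (average direct and causal mediation
    effects) through childhood BMI. Includes an LD-blocked synthetic-cohort
    generator that emulates the full data structure (summary statistics,
    genotypes, phenotypes, missing-at-random attrition) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
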