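Package: sorgal
Title: Aluminum Tolerance and Population Structure Analysis for Sorghum
    Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for dissecting aluminum (Al)
    tolerance in cultivated sorghum diversity panels. Computes hydroponic
    root-growth tolerance indices (relative net root growth, induction of
    root growth, relative root growth, visual root damage), clusters
    accession means with the Scott-Knott likelihood test and summarises
    indices by principal components; derives SSR allele statistics,
    polymorphism information content and proportion-of-shared-alleles
    kinship; fits a Bayesian admixture model to multi-allelic SSR
    genotypes by Gibbs sampling with Evanno delta-k model-order
    diagnostics; estimates degree of dominance (d/a) from parent and F1
    means and maps backcross marker-trait linkage by single-marker and
    Haley-Knott interval analysis; and runs the structured-association
    stage: Kruskal-Wallis tests with non-parametric lsd letters, the Q+K
    unified mixed model with shared-allele kinship, BIC-based sequential
    subpopulation exclusion and structure R-squared. A synthetic-data
    generator with Balding-Nichols subpopulation differentiation and a
    rare major tolerance locus provides ground truth for every stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
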