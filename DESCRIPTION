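Package: cpcage
Title: Constrained Principal Component Analysis with Gene-Environment
    Interactions for Neonatal Brain Volumetrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native implementation of constrained principal
    component analysis (CPCA) for subcortical brain-volume cohorts of very
    preterm children. The external analysis partitions a standardized
    subject-by-region volume matrix into a main-effect space (neonatal
    clinical factors, total brain volume, genotypes), a gene-by-environment
    interaction space, and a residual; the internal analysis extracts
    principal components of each predicted space. Inference on component and
    predictor loadings uses a case-resampling bootstrap with component
    alignment, percentile confidence intervals and p-values, and
    Benjamini-Hochberg / Bonferroni multiplicity adjustment. Component
    scores are correlated with neurobehavioral outcome measures. A synthetic
    cohort generator with Hardy-Weinberg genotypes and a planted low-rank
    linear volume model makes every stage testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
RoxygenNote: 7.3.3
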