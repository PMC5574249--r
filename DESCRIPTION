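Package: brcaness
Title: Expression-Based BRCA1-Like Classification and Trial Biomarker
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a gene-expression surrogate ('BRCA1ness') for the DNA
    copy-number 'BRCA1-like' phenotype of triple-negative breast tumours and
    evaluates it as a predictive biomarker in a two-arm neoadjuvant trial.
    Implements the microarray preprocessing chain (background offset + log2,
    quantile normalisation, low-signal flagging, k-nearest-neighbour
    imputation, batch location/scale adjustment, probe summarisation by first
    principal component), diagonal linear discriminant analysis with
    leave-one-out cross-validated gene-set-size selection by ROC AUC, a
    portable nearest-centroid diagnostic with a correlation-difference score
    and fixed threshold, and trial statistics (per-arm Fisher tests and odds
    ratios, biomarker-by-treatment interaction likelihood-ratio tests with
    covariate adjustment, baseline-characteristics chi-squared tables).
    A synthetic-data module generates discovery cohorts and trial tables with
    the statistical structure the analysis assumes.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
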