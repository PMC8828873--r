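Package: sig32
Title: Pathway-Derived Gene Signatures, Molecular Subtypes and Survival
    Risk Scores for Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable implementation of a gastric-cancer biomarker pipeline:
    ranking of cancer-type-specific altered pathways from pan-cancer somatic
    mutations by network-regularized non-negative matrix tri-factorization
    with permutation-based false discovery control; extraction of a pathway
    gene signature; consensus non-negative matrix factorization subtyping of
    tumour expression profiles with cophenetic/CDF diagnostics; all-pairs
    linear support-vector-machine subtype classification; a linear SVM risk
    score for five-year overall survival; and the accompanying survival and
    treatment-response statistics (Kaplan-Meier/log-rank, multivariable Cox,
    treatment-adjusted survival curves, bootstrap lasso-Cox, chi-square and
    one-way ANOVA). A synthetic-cohort generator with planted pathway,
    subtype, survival and response structure supports parameter-recovery
    testing without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    e1071,
    glmnet,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
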