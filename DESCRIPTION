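Package: pcafe
Title: Unsupervised PCA-Based Feature Extraction for Categorical
    Multiclass Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction (FE) for expression data observed under many
    unordered conditions, where supervised contrasts are weak or labels are
    unreliable. Implements a feature-dependent extension of variational Bayes
    PCA in which the prior variance of each feature score carries automatic
    relevance determination (VBPCAFE), and its lightweight counterpart based
    on conventional PCA outlier selection (CPCAFE), together with three
    supervised baselines (one-vs-one t tests, categorical regression, and
    BAHSIC backward elimination with a linear-kernel HSIC), a Gaussian
    mixture simulator for categorical multiclass benchmarks scored by the
    Matthews correlation coefficient and F measure, and downstream
    integration utilities for miRNA-mRNA analysis: negative-correlation
    screening with t-based significance, 7mer-m8 seed matching, group-wise
    differential tests, and cross-validation stability counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
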