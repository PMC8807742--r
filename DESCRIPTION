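Package: widoc
Title: Cell-Type-Aware DNA Methylation Risk Index from Cervical Smears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a DNA-methylation risk index (the WID-OC
    index) from heterogeneous cervical-smear beta values. Implements
    cell-type-aware differential methylation via the intercept method,
    reference-based cell-type deconvolution with tumour-DNA fraction
    estimation and loess residual correction, penalized-logistic index
    training with an index-size sweep, beta-mixture variance attribution
    with known immune mixing weights, in-silico tumour-DNA contamination
    simulation, and the evaluation layer: rank-based AUC with DeLong
    confidence intervals, median-unbiased (mid-p) odds ratios for quartile
    tables and genomic-region enrichment, polygenic risk scores, and
    MethyLight PMR. A synthetic-methylome generator provides cohorts with
    known cell-fraction and effect structure so the whole pipeline is
    testable without access-restricted array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
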