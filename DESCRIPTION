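Package: parenclitic
Title: Parenclitic Network Mapping of Physiological Laboratory Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population correlation network maps and individual parenclitic
    deviations for critically ill patient cohorts. Builds Bonferroni-gated
    Pearson correlation networks over a 15-variable routine laboratory panel
    using pairwise deletion, fits orthogonal (total least squares) regression
    lines on a reference population for each significant variable pair, and
    scores every patient by the orthogonal distance of their data point from
    each reference line. Includes the downstream survival-evaluation battery
    (Mann-Whitney comparison with effect sizes, multivariate Cox
    proportional-hazards models on z-normalized deviations, ROC analysis with
    DeLong confidence intervals and Youden cut-offs, Kaplan-Meier estimation
    with log-rank tests) and a synthetic sepsis-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
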