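Package: podspace
Title: Multi-Scale Behavioural Phenotyping of Delirium-Like Behaviour in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for postoperative-delirium-like behaviour in
    mice from 3-D skeleton trajectories and movement-module labels: pose
    featurization (50-bin probability mass functions summarised into
    descriptor vectors), an EDF-resampling two-sample Kolmogorov-Smirnov
    test, geometric detection of object-investigation bouts with deep versus
    shallow preference (DSP), movement-fraction statistics with Sidak-adjusted
    discriminative-movement selection, diagnosis of delirium-like animals in
    a low-dimensional behaviour space (exact t-SNE embedding, linear
    decision boundary, signed projection values), hyperactive/hypoactive
    subtype clustering, and cross-validated logistic classification of
    treatment effects with incidence estimates. Includes a seeded synthetic
    session generator so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
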