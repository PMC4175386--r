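Package: svmtaguchi
Title: Multiclass SVM Classification with SVM-RFE Feature Ranking and
    Taguchi Parameter Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage toolkit for multiclass classification of
    tabular (UCI-style) datasets with support vector machines. Features
    are ranked by SVM recursive feature elimination (SVM-RFE) using the
    squared components of the linear decision-function weight vector;
    the penalty parameter C and the RBF kernel parameter gamma are then
    tuned by a Taguchi L9(3^2) orthogonal-array experiment scored with
    the larger-the-better signal-to-noise ratio; the final classifier
    decomposes the K-class problem by one-against-all, one-against-one
    voting, or a decision directed acyclic graph, and is evaluated by
    stratified repeated k-fold cross-validation. Includes deterministic
    synthetic-data generators emulating ordinal and boolean UCI schemas,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
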