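Package: fsace
Title: Feature Selection by Approximate Conditional Entropy on Fuzzy
    Information Granules
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Filter feature selection for high-dimensional classification
    data such as gene expression matrices. Objects are granulated by a
    Laplacian-kernel fuzzy similarity relation discretized through a k-bin
    approximately-equal relation; knowledge uncertainty is scored by an
    approximate conditional entropy that damps each decision-class term by
    the class's rough-set approximation accuracy, blending boundary-region
    imprecision with information granularity; a greedy forward search
    (FSACE) selects a minimal attribute subset preserving that entropy.
    Includes a synthetic decision-table generator with known ground truth,
    a stratified cross-validation harness (kNN, CART, RBF least-squares
    SVM), a sigma-sweep protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
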