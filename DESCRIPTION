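Package: possclass
Title: Possibilistic Clustering-Promoting Semi-Supervised Kernel Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-supervised kernel classification under a possibilistic
    clustering assumption. A kernel decision function and a per-class label
    membership function are optimized alternately in closed form; each
    instance is tied to the local weighted mean (LWM) of its k nearest
    neighbours, and a fuzzy-entropy regularizer lets outliers receive low
    membership in every class rather than being forced into one. Includes
    the hard-assignment variant, multi-kernel Gram combination, consistency
    diagnostics between the two prediction routes, a synthetic-problem
    generator for Gaussian class blobs with scarce labels and shell
    outliers, delimited-text and JSON model input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
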