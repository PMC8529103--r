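Package: cuporigin
Title: Tissue-of-Origin Classification for Cancer of Unknown Primary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating gene-expression tissue-of-origin
    classifiers for cancer of unknown primary (CUP). Implements marker-panel
    selection by per-type support vector machine recursive feature elimination
    (SVM-RFE), a one-vs-rest linear classifier with Platt-calibrated similarity
    scores that sum to 100 across tumor types, specimen quality-control gating,
    median-of-ratios count normalization, location-scale batch correction, a
    PCA centroid-concordance validation, and concordance reporting against
    reference diagnoses. A negative-binomial pan-cancer simulator with planted
    type-specific markers, attenuated metastasis queries, library-size
    variation and batch effects supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
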