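Package: screendx
Title: Diagnostic Accuracy and Dual Cut-Offs for Discrete Cognitive Screening Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating discrete cognitive screening instruments
    (0-30 integer scores such as the MoCA and MMSE) against clinical diagnostic
    groups. Implements per-threshold accuracy metrics, empirical ROC curves with
    the Mann-Whitney AUC estimator and a paired stratified-bootstrap test for
    correlated AUCs, four single cut-off strategies (fixed, balanced, Youden
    index, percentile-in-controls), predictive values as a function of
    prevalence, and a dual-cut-off procedure that separates a "not healthy" and
    a "not pathological" threshold by an indecisive score band built from
    cumulative frequency curves. Ships a synthetic memory-clinic cohort
    generator with published group-level parameters so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
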