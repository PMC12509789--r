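Package: failbench
Title: Failure-Aware Method Comparison for Simulation and Benchmark Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparison studies in which one or more methods fail to
    produce a result on some data sets. Provides failure-aware results
    bookkeeping, the common handling strategies (discarding data sets for the
    failing methods only or for all methods, imputation by the worst value, by
    the mean of the other methods, by the method's own mean, hybrid and
    weighted rules), fallback-pipeline evaluation, failure-proportion
    reporting, and a slimmed-down three-part report. Includes two worked
    simulation studies: odds-ratio estimation for 2x2 tables under sampling
    zeros (manual, Woolf, conditional-MLE, mid-p and small-sample estimators
    with the Haldane-Anscombe correction as a fallback) and coverage of naive
    versus variance-corrected resampled t-intervals for the generalization
    AUC of a classification tree under subsampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
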