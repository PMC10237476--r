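Package: fibpulse
Title: High-Frequency Fecal Indicator Bacteria Variability and Driver Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency (subhourly) time series of
    fecal indicator bacteria (FIB) concentrations at recreational beaches
    together with co-measured environmental covariates. Provides
    censoring-aware ingest and feature engineering for left-censored MPN
    concentration data, the normalized adjacent-sample variability statistic
    delta_i with a downsampling analysis across sampling intervals, lagged
    Spearman cross-correlation screening with per-variable lag selection,
    grouped Kruskal-Wallis comparisons, and a two-part hurdle model of FIB
    concentration (random-forest detection part with permutation-importance
    pruning; generalized-least-squares concentration part with second-order
    autoregressive errors and iterative variance-inflation-factor pruning).
    A synthetic-data generator emulating tidal and diel covariate structure
    with serially correlated noise and a left-censored lagged log-linear FIB
    response makes the whole pipeline exercisable and testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
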