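Package: jierp
Title: Joint-Interval Event-Related Potential Analysis of Tactile EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Separates tactile-evoked EEG potentials by the joint
    distribution of the previous and penultimate inter-stimulus intervals
    (the JIERP), and characterizes interval-dependent signal modulation via
    mass-univariate FDR statistics, Spearman latency cross-correlation, and
    stability-selected non-negative matrix factorization with k-means
    clustering of factor loadings across a population. Includes a synthetic
    stimulation-train and EEG generator so every stage of the analysis is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    cluster,
    jsonlite,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
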