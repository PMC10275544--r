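Package: megconn
Title: Band-Limited Functional Connectivity Networks and Weighted Graph
    Metrics for Multichannel Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds resting-state functional-connectivity networks from
    multichannel neural time series (for example beamformed MEG virtual
    sensors): zero-phase decomposition into canonical frequency bands
    (delta through ripple), zero-lag Pearson correlation between channel
    pairs, and an edge threshold derived from the t statistic of a
    correlation coefficient. Surviving signed networks are summarised with
    weighted graph-topology metrics (degree, strength, characteristic path
    length with inverse-weight edge lengths, geometric-mean clustering
    coefficient) and compared across groups with a normality-gated
    ANOVA/Kruskal-Wallis workflow, Bonferroni-corrected pairwise tests and
    metric-score correlations. A deterministic synthetic-cohort generator
    (coupled band-limited sources, optional spike-and-slow-wave
    transients) lets the whole chain run without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
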