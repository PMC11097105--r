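Package: phragnet
Title: Salt-Tolerance Evaluation and Co-Expression Screening for Tidal-Flat
    Reed Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical chain for evaluating salt tolerance of Phragmites
    australis stands along a tidal-flat gradient: shoot functional-trait
    metrics (SLA, LDMC, coefficients of variation, summary-statistics
    one-way ANOVA), a fuzzy membership-function comprehensive tolerance
    score (D value), weighted co-expression network analysis with
    topological overlap and dual-depth salinity module screening,
    negative-binomial exact-test differential expression with TMM
    normalization, intersection-based core-gene screening, Pearson
    correlation gene networks with hub identification, and Fisher
    exact-test enrichment.  Includes a synthetic-data generator that
    plants the statistical structure every stage assumes, so the whole
    chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mclust,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
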