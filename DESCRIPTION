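Package: provtrial
Title: Quantitative Genetics of Forest-Tree Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of randomized complete block provenance trials in
    forest trees: derived growth and wood traits (stem volume, wood basic
    density, cellulose crystallinity, slenderness ratios), descriptive
    summaries with Duncan's multiple range test, REML estimation of
    provenance and provenance-by-block variance components on unbalanced
    data by an EM algorithm with average-information acceleration,
    provenance heritability with the harmonic-mean correction for unequal
    plot sizes, genetic and phenotypic correlations, realized gain and
    superior-provenance selection, and binary quadratic trend-surface
    analysis of geographic variation. Includes a synthetic-trial generator
    with the exact statistical structure of the mixed model so every stage
    can be tested by parameter recovery.
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
    lme4,
    yaml
Config/testthat/edition: 3
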