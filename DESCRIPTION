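Package: ampliscreen
Title: Amplicon-Based Carrier Screening and GAA Repeat Expansion Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted amplicon carrier screening for founder populations: a
    GRanges-backed data model for a screening panel of recessive
    disease-causing variants, a multiplex amplicon read simulator with
    configurable cohort structure and allele frequencies, a threshold-based
    diploid genotyper for SNVs and small indels, a split-read caller for
    Friedreich ataxia GAA repeat-expansion carriers based on per-read repeat
    counts (repeat-per-read frequencies), and cohort statistics: carrier
    frequencies with Wilson confidence intervals, per-gene aggregation,
    at-risk-couple probabilities, and screening-panel filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'panel.R'
    'amplicons.R'
    'simulate.R'
    'genotype.R'
    'frda.R'
    'stats.R'
    'pipeline.R'
    'ampliscreen-package.R'
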