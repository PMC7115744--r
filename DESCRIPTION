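Package: adipoDyn
Title: Depot-Specific Gene Expression Dynamics During Adipogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores genes for divergent expression dynamics between two
    adipose depots across a differentiation time course. Provides
    detection-above-background expression filtering, four transcript
    time-course divergence scores (dynamic, peak, interval integrals,
    literature relevance) combined into a consensus score, robust-z
    significance and instability flagging, upper-quartile candidate
    selection, k-means clustering of expression-slope vectors with a
    rise/constant/fall pattern grammar and congruent-versus-divergent
    dynamics classification, and paired-cohort association statistics
    (Spearman correlation, Mann-Whitney tests, covariate-adjusted
    regression). A synthetic-data module generates time-course
    experiments, per-exon detection p-value tables, and paired cohorts
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TimeCourseExperiment.R'
    'archetypes.R'
    'clustering.R'
    'cohort.R'
    'filter.R'
    'io.R'
    'pipeline.R'
    'scoring.R'
    'simulate.R'
    'utils.R'
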