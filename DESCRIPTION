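Package: metaboDrift
Title: Age-Associated Feature Discovery in Untargeted CSF Metabolomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a cerebrospinal-fluid (CSF)
    untargeted metabolomics workflow for finding metabolite features
    associated with chronological age. Provides a SummarizedExperiment-based
    container for LC-MS feature tables with injection metadata; a synthetic
    cohort generator with planted age, gender, contaminant and drift
    structure for end-to-end validation; the quality-control filtering
    chain (sample-presence rule, blank-contaminant removal, dilution-series
    Pearson filter, pooled-QC LOESS run-order correction, QC
    coefficient-of-variation filter); distance-based redundancy analysis
    (dbRDA) with permutation tests and post-hoc goodness-of-fit;
    Boruta-style shadow-feature selection over random forests with
    regression-tree validation; hierarchical clustering of samples and
    features with a dynamic-time-warping linearity score; and putative
    annotation utilities (monoisotopic adduct masses, ppm library matching,
    MSI-level bookkeeping, compound-class Fisher enrichment, and chemical
    ontology pruning and treemap aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    limma,
    ranger,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
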