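Package: typebias
Title: Collection-Bias Analysis of Herbarium Type Specimen Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify taxonomic, temporal and spatial bias in
    herbarium type-specimen records, built around the Fabaceae type
    collections of Mozambique as the reference use case. Provides
    Darwin-Core-style record ingestion and validation, a weighted
    min-max-normalised collector-importance index with rank-stability
    analysis, decade-level discovery accumulation curves and
    collection-to-publication lag statistics, two-dimensional kernel
    density surfaces of collection effort, assignment of records to
    named spatial units (provinces, ecoregions, centres of endemism,
    important plant areas), construction of presence/pseudo-absence
    predictor tables from elevation, slope, land-cover and
    accessibility layers, and a binomial-logit model of collection
    probability fitted by iteratively reweighted least squares with
    AICc model selection, McFadden pseudo-R2 and ROC AUC. A synthetic
    landscape and collection-history generator with known ground truth
    makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
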