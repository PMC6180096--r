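Package: promhic
Title: Promoter Capture Hi-C Interaction Calling, Differential Contact
    Analysis and Regulatory Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing promoter-centred chromatin interactomes
    between two cell types from promoter capture Hi-C (PCHi-C) fragment-pair
    count data. Implements a coverage-product binomial background test for
    significant promoter-genome interactions with per-promoter significance
    thresholds derived from the inflection of each promoter's cumulative
    significance curve; a two-condition differential interaction caller that
    uses reference-condition counts as expected values with covariate-weighted
    (independent-hypothesis-weighting style) false discovery rate control;
    homotypic chromatin-mark interaction classification and three-state
    enhancer annotation (active, poised, intermediate) from peak calls;
    expression integration with k-means profile clustering and enrichment
    summaries; and a fully seeded synthetic-data generator with planted ground
    truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
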