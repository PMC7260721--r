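Package: stressnet
Title: Cross-Study Transcriptomic Meta-Analysis and Regulatory Network
    Inference for Nutrient Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying genes jointly regulated by
    nutrient stresses across independent expression studies and for
    nominating hub transcription factors. Implements quantile
    normalization and probe-to-locus collapsing, per-study differential
    expression with empirical-Bayes moderated t-statistics and
    Benjamini-Hochberg adjustment, inverse-normal (Stouffer) cross-study
    combination with calling of common stress-responsive genes, gene-set
    overlap statistics (overlapping coefficient, hypergeometric
    enrichment, Venn partitions), k-means profile clustering and PCA,
    Pearson-correlation co-expression networks with edge significance
    filtering and hub ranking, and directed TF-to-target network
    inference by random-forest feature importance with prior-weighted
    regulator sampling. Ships a synthetic multi-study data generator
    with planted ground truth so every stage is testable end to end,
    plus small phenotype measurement formulas (wavy root index,
    growth-arrest fraction with Wilson intervals, qPCR
    delta-delta-Ct relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    ranger,
    igraph,
    jsonlite,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
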