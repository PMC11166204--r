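Package: proxiScore
Title: Scoring, Filtering and Annotation of Proximity-Labeling Interactomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for post-processing SAINT-scored proximity-labeling (BioID)
    screens run in parallel cell lines. Implements replicate quality control
    (Spearman correlation gate and multidimensional-scaling grouping checks),
    CompPASS-style WD specificity scores and their across-cell-line sum (WDS),
    membrane-control (CAAX) enrichment ratios, complexity-based normalized
    spectral counts (CBNP), a calibrated high-confidence filter stack with
    ROC/Youden and cumulative-distribution cutpoint estimation against a
    gold-standard edge list, effector clustering with Ward linkage and
    silhouette-guided cluster-number selection, marker-based subcellular
    localization calls, and a negative-binomial synthetic-screen generator
    with planted ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    mclust,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Clustering, QualityControl
RoxygenNote: 7.3.3
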