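Package: herbassess
Title: Preliminary Conservation Assessment of Plant Species from Herbarium Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rapid, reproducible triage of plant species into
    threatened and not-threatened classes from herbarium specimen occurrence
    records. Computes the geographic range metrics that underpin IUCN Red
    List criterion B (extent of occurrence as a minimum convex polygon, area
    of occupancy on a 2 x 2 km grid, and a grid-based estimate of the number
    of locations), implements four rule-based preliminary classifiers
    (EOO-band categorisation, a criterion-B approximation with assumed
    continuing decline, a specimen-count threshold rule, and a decision-tree
    triage using specimen counts, locality breadth and collection dates),
    and a random-forest classifier trained on per-species predictors with a
    repeated cross-validation protocol and out-of-bag permutation
    importance. Classifier performance is scored against reference Red List
    categories (accuracy, sensitivity, specificity, default accuracy) and
    differences between classifiers are judged by Bayesian estimation with
    conjugate Beta/Dirichlet posteriors and 95 percent credible intervals.
    A synthetic herbarium-data generator with known ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
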