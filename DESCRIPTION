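Package: molsig
Title: Graph-Based Molecular Signatures for Anticancer Bioactivity Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurizes small molecules as graph-based signatures: cumulative
    counts of pharmacophore-class atom pairs within increasing shortest-path
    distance cutoffs on the heavy-atom molecular graph, concatenated with
    general physicochemical descriptors into a fixed 264-dimensional vector.
    Provides growth-inhibition activity labeling in the NCI-60 style,
    non-redundant train/blind splitting by Butina clustering on circular
    fingerprints, greedy forward feature selection, ensemble-tree
    classification and per-cell-line GI50 regression with 10-fold
    cross-validation, substructure enrichment and Kolmogorov-Smirnov
    property comparisons, and a synthetic-data generator with a planted
    substructure-activity relationship for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    ranger,
    randomForest,
    xgboost,
    ggplot2,
    stats,
    utils,
    generics,
    class,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
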