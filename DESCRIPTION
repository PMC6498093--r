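Package: compartmiR
Title: Compartment-Resolved miRNA Biomarker Selection with Monte-Carlo
    Feature Selection and RIPPER Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the discriminative power of circulating
    miRNA profiles measured in different blood compartments (whole plasma,
    extracellular vesicles, and vesicle-depleted plasma). Features are
    ranked by Monte-Carlo feature selection: many decision trees are grown
    on random feature projections and every feature accumulates a relative
    importance score from the information gain of its tree nodes, weighted
    by tree accuracy and node size. Interpretable threshold rules are then
    learned with a from-scratch RIPPER (Repeated Incremental Pruning to
    Produce Error Reduction) implementation, and performance is estimated
    by repeated stratified k-fold cross-validation with pooled confusion
    matrices and weighted (class-balanced) accuracy. Cross-compartment
    comparison covers top-k signature overlaps, class means and fold
    changes, and Ward.D2 hierarchical clustering of samples. A synthetic
    data generator produces compartment-structured, zero-inflated count
    matrices with planted marker features so the whole pipeline can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
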