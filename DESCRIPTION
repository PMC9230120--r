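Package: geneconf
Title: Confidence Scoring of Annotated Gene Models from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scores annotated plant gene models as high- or low-confidence
    from sequence alone. Computes 14 nucleotide features (GC composition,
    codon-position GC, skew heterogeneity, melting temperature, k-mer
    entropy, DEFLATE compression ratio, codon adaptation index, start/stop
    flags) and 41 protein physicochemical features (residue and class
    composition, molecular weight, isoelectric point, GRAVY, instability,
    windowed flexibility, molar extinction, aliphatic indices) per gene
    model, labels genes from precomputed homology-search evidence, trains
    gradient-boosted decision-tree classifiers with Gaussian-process
    Bayesian hyperparameter search, evaluates them (ROC, precision-recall,
    F1, MCC, cross-validation), and explains predictions with split-gain
    importances and exact tree Shapley attributions. Includes a synthetic
    paired CDS/protein corpus generator with planted class structure for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    lhs,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
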