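Package: microexplore
Title: Exploratory Analysis of Microbiome and Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A study-centric engine for exploratory analysis of sample-by-feature
    abundance tables (amplicon sOTU tables, metabolomics MS1 bucket tables).
    A FeatureExperiment object keeps the abundance matrix synchronized with
    sample and feature metadata and records an operation history. The package
    provides compositional normalizations and transforms (total sum scaling,
    outlier-excluding TSS, centered log-ratio, log, binarization), metadata and
    data-driven filtering, sorting and single-linkage clustering for heatmap
    ordering, permutation-based nonparametric differential-abundance and
    correlation tests with discrete FDR (dsFDR), Benjamini-Hochberg and
    filtered-BH control, a local ontology-annotation store with rank-based
    term-enrichment testing, and deterministic static heatmap rendering with
    self-contained HTML export. A command-line interface chains the steps via
    on-disk experiment bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    Matrix,
    biomformat,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
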