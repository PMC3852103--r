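Package: outlierDE
Title: Heterogeneity-Aware Outlier Differential Expression and Consensus
    Pathway Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cancer outlier expression profiles -- features over- or
    under-expressed in only a subset of tumour samples -- with six two-group
    statistics (Student's t, COPA, Outlier Sum, Outlier Robust T, MOST and
    LSOSS), selects per-method top-quantile feature sets, and evaluates the
    methods by cross-method consensus ("putative outlier" agreement) across
    multiple datasets. Downstream stages map consensus differentially
    expressed microRNAs to target genes via user-supplied prediction tables
    (with an intersection rule for combining predictors), compute a
    cross-dataset target-gene consensus, and test the consensus genes for
    gene-set over-representation with the hypergeometric distribution and
    Benjamini-Hochberg false discovery rate control. A synthetic-data
    module generates multi-platform expression scenarios with planted
    outlier features, target maps and gene-set collections so the whole
    workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
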