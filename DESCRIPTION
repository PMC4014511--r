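Package: semde
Title: Muscle-Contrast Microarray Differential Expression with
    GO Semantic-Similarity Clustering and qPCR Validation
Version: 0.1.0
Authors@R:
    person("Genmascq", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-tissue microarray contrast studies:
    per-spot quality filtration, natural-log transformation with within-sample
    median centering, outlier masking, k-means low-variability filtering,
    per-probe fixed-effects linear models with backward effect retention,
    Benjamini-Hochberg false discovery rate control, least-squares adjusted
    means and fold-change calling; Wang graph-based Gene Ontology semantic
    similarity with best-match-average gene similarity; Ward hierarchical
    clustering on 1 - similarity; per-cluster hypergeometric term and pathway
    enrichment against a chip background; and a geNorm-normalized RT-qPCR
    validation arm.  A synthetic-data module generates expression matrices,
    ontologies, annotations and Ct tables with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
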