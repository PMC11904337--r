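Package: pbconsensus
Title: Consensus Pseudobulk Differential Expression for Droplet scRNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case-control droplet single-cell RNA-seq
    cohorts: adaptive per-sample quality control (UMI, gene, mitochondrial
    and hemoglobin filters with a grid-rounded 95th-percentile mitochondrial
    threshold), artificial-doublet nearest-neighbour scoring, a
    batch-dependent ambient-RNA gene metric estimated from low-count
    barcodes, pseudobulk aggregation per sample and cell type, three
    independent differential-expression engines (negative-binomial Wald
    GLM, negative-binomial exact test, and precision-weighted moderated-t),
    a consensus significance rule across the engines, fold-change fusion by
    the first principal component for gene ranking, pre-ranked gene set
    enrichment with permutation-normalised enrichment scores, and
    baseline-characteristics cohort statistics. Includes a synthetic cohort
    generator with planted effects, doublets, empty droplets and shared
    ambient contamination so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
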