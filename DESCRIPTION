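Package: mixturetox
Title: Comparative Whole-Mixture Toxicogenomics for Developing Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the biological activity of whole
    environmental mixtures in developing zebrafish. Implements
    negative-binomial differential expression with a common dispersion
    shared across treatment groups, MDS-based sample outlier screening,
    cross-mixture concordance and through-the-origin effect-ratio
    regression, k-means/hierarchical heatmap structure and treatment-level
    PCA, hypergeometric gene-set overrepresentation with term-size
    filtering, enrichment-map network construction with
    overlap-coefficient edges, Jaccard-distance term-redundancy
    reduction, developmental-screen dose-response statistics
    (Clopper-Pearson intervals, Fisher's exact comparisons, plate QC),
    and PAH chemistry summaries (totals with propagated confidence
    intervals, source-diagnostic ratios, composition profiles). A
    synthetic-data module generates count matrices, gene-set
    collections, screen tables and chemistry tables with planted ground
    truth for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    yaml,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    edgeR,
    DESeq2,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
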