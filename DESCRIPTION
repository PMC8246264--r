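Package: splicekit
Title: Alternative Splicing, Motif Enrichment, Exon Orthology and Behavior
    Analysis for Muscleblind-Family Loss-of-Function Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing alternative-splicing misregulation in
    muscleblind (MBNL) loss-of-function models. Reads rMATS-style event
    tables, classifies regulated cassette exons by FDR and inclusion-level
    change, builds consensus event sets across genotypes, quantifies YGCY
    motif enrichment around regulated cassette exons against
    composition-matched control 4-mers, calls orthologous exons between
    species with a translated local aligner, clusters samples on the most
    variable splicing events via the gap statistic and K-means, computes
    swim-trajectory kinematics (pause segmentation, fastest-window speed,
    vertical position), and provides the accompanying statistics layer
    (one-way ANOVA with Tukey comparisons and compact letter displays,
    Spearman correlation, Benjamini-Hochberg FDR, chi-square goodness of
    fit, and comparative C_T expression). Includes synthetic-data
    generators so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
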