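Package: mirDevScreen
Title: Integrated mRNA/miRNA Developmental Expression Analysis and
    Anti-Correlation Regulator Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for integrated mRNA and miRNA developmental
    time-course expression analysis of paired organs: CPM detection
    filtering, three-criterion negative-binomial differential expression
    against an embryonic baseline (FDR, fold change, replicate direction
    consistency), clustering of standardized condition profiles into shared
    and organ-specific programs, hypergeometric gene-set and predicted-target
    over-representation with enrichment factors, and an anti-correlation
    screen that nominates candidate regulator miRNAs. Includes a synthetic
    data generator with planted profile archetypes and repressor miRNAs so
    every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'clustering.R'
    'diffexp.R'
    'enrichment.R'
    'io.R'
    'mirDevScreen-package.R'
    'pipeline.R'
    'preprocess.R'
    'screen.R'
    'simulate.R'
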