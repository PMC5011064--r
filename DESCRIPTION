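Package: twinGxE
Title: Gene-by-Adiposity Interaction eQTL Mapping in Twin Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering context-specific regulatory variation in
    twin-structured transcriptome studies, where a continuous physiological
    exposure such as body mass index modifies the effect of a cis or trans
    regulatory variant on exon-level expression. Implements meta-exon
    construction and rank-based inverse normal transformation of exon
    quantifications, twin-aware linear mixed-model phenotype association
    with likelihood-ratio testing, latent-factor confounder estimation and
    residualization, cis and trans genotype-by-phenotype interaction scans
    with an exon-stratified permutation false discovery rate, Storey
    pi0/pi1 sharing statistics, Sobel mediation analysis of trans networks,
    and regulatory trait concordance colocalization scoring. A synthetic
    twin-cohort generator with planted effects makes the full pipeline
    testable end to end without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: GeneExpression, SNP, GeneticVariability, Transcriptomics,
    StatisticalMethod, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
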