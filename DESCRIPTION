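Package: heatgrad
Title: Gradient Heat-Stress Phenotype and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-genotype stress-gradient experiments:
    mixed-model adjusted entry means and repeatability for phenotypic
    traits, a PCA-based multi-trait heat susceptibility index (HSI),
    negative-binomial dose-response regression of gene expression over
    metric-coded heat levels (overall and per genotype), intersection
    analysis of responsive gene sets, a second-stage regression of
    per-genotype expression slopes on the HSI to call heat-tolerance
    genes, and hypergeometric category enrichment. Includes synthetic
    data generators with planted effects for every stage, FASTQ
    quality/adapter filtering, CPM filtering, TMM normalization and
    common-dispersion (BCV) estimation, plus an end-to-end pipeline
    runner with TSV artifacts and a plain-text report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    lme4,
    lmerTest,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, Regression,
    Normalization, QualityControl
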