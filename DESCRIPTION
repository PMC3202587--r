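Package: coralqpcr
Title: Efficiency-Calibrated qPCR Analysis of Heat-Light Stress in Corals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for qPCR-based gene expression analysis of acute
    heat-light stress in reef-building corals. Converts raw crossing-point
    (CP) tables into efficiency-calibrated log2 abundance (Ca) values,
    normalizes against internal control genes, ranks candidate reference
    genes by geNorm expression stability, performs gene-wise
    differential-expression inference with linear mixed models and
    false-discovery-rate control, and computes the two-gene Porites Stress
    Index (PSI) diagnostic together with PCA-based marker selection. A
    synthetic-data generator reproduces the paired-colony experimental
    designs, amplification-efficiency calibration series and variance
    structure that the analysis assumes, enabling parameter-recovery
    testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, DifferentialExpression, Normalization
RoxygenNote: 7.3.3
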