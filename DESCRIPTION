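Package: gliofrag
Title: Fragmentomics and Tumor-Guided Mutant-Read Integration for Glioma Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cell-free DNA (cfDNA) fragment-size analysis and
    tumor-guided mutant-read integration in liquid biopsies (urine, plasma,
    cerebrospinal fluid) of glioma patients. Implements fragment-length
    extraction from paired-end alignments, size-profile statistics (medians,
    empirical CDFs, Kolmogorov-Smirnov distances, 30-bp bin proportions), the
    10-bp nucleosomal oscillation amplitude statistic, the integrated mutant
    allele fraction (IMAF) with control-based locus blacklisting and binomial
    outlier suppression, and grouped repeated cross-validation classification
    of cancer versus control samples with four model families. A calibrated
    synthetic cohort generator reproduces the statistical structure the
    analysis assumes, so the whole pipeline is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
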