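Package: uripanel
Title: Urinary Peptide Biomarker Panels for Significant Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating urinary
    peptide biomarker panels that discriminate clinically significant
    (Gleason score >= 7) from non-significant prostate cancer using
    CE-MS-style peak-list data. Provides a synthetic cohort generator
    with planted case-control effects, internal-standard normalisation
    and log transformation, stability-filtered Wilcoxon/Benjamini-Hochberg
    biomarker discovery, a support-vector-machine panel classifier with a
    discovery-set cutoff, and a validation and clinical-utility suite:
    ROC curves with DeLong variance, exact binomial confidence intervals,
    Kruskal-Wallis comparisons across Gleason strata, logistic nomograms
    and decision-curve analysis of net benefit. All user-facing functions
    take data frames and return tibbles so steps chain with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
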