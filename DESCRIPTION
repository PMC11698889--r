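Package: laquant
Title: Quantitative LA-ICP-ToF-MS Elemental Bioimaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of multi-element images from
    laser-ablation inductively-coupled-plasma time-of-flight mass spectrometry
    (LA-ICP-ToF-MS) bioimaging of tissue sections. Provides rolling-median
    outlier filtering, per-element k-means intensity thresholding to mask glass
    background and irrelevant tissue, external calibration against
    matrix-matched gelatine standards with limits of quantification,
    response-factor normalization of uncalibrated elements, region summaries
    (median with quartiles), nonparametric group and paired comparisons
    (Mann-Whitney U, Wilcoxon signed-rank), Spearman colocalization, and a
    ground-truthed synthetic phantom generator for validating every stage of
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    tibble,
    dplyr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
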