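Package: ibrtox
Title: Integrated Biomarker Response (IBRv2) Analysis for Multi-Biomarker
    Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-biomarker ecotoxicology exposure
    studies from raw microplate readings to an integrated stress score.
    Converts kinetic and endpoint microplate assays into blank-corrected,
    protein-normalised biomarker endpoints; computes cellular energy
    allocation (CEA = Ea - Ec) from energy reserves and consumption;
    runs an assumption-driven group-comparison engine (Shapiro-Wilk
    normality cascade with square-root and natural-log transforms,
    Levene's test, one-way/Welch ANOVA or Kruskal-Wallis, Tukey,
    Games-Howell or Dunn-Bonferroni post hocs, omega-squared and
    epsilon-squared effect sizes); and scores grouped responses with the
    Integrated Biomarker Response version 2 (IBRv2), including radar-plot
    data. A synthetic study generator with a known ground truth supports
    calibration, power analysis and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    withr,
    car,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
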