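Package: radburden
Title: Allele-Level Association and Risk-Allele Burden for Radiation-Induced
    Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of candidate-gene SNP panels against severe
    late radiotherapy toxicity. Builds per-SNP 2x2 allele-count tables from
    genotype dosage matrices and RTOG/EORTC fibrosis grades, estimates odds
    ratios with Woolf confidence intervals (Katz risk-ratio fallback for
    zero-control-variant tables), tests association by Pearson chi-square with
    a Fisher exact fallback under Cochran's rule, applies Bonferroni
    correction, scores each patient's cumulative risk-allele burden across
    significant loci, and compares groups by the Mann-Whitney rank-sum test.
    Includes a Hardy-Weinberg cohort simulator with configurable per-allele
    odds ratios for calibration (type I error, power, parameter recovery) and
    report formatters for publication-style allele-frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
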