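Package: targetMR
Title: Drug-Target Two-Sample Mendelian Randomization from GWAS Summary
    Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-sample Mendelian randomization with cis (drug-target)
    instruments built from GWAS summary statistics. Provides summary-statistic
    reading and allele harmonization with palindromic-variant handling,
    gene-window and genome-wide LD clumping, instrument-strength and power
    reporting, a full estimator suite (Wald ratio, fixed and multiplicative
    random-effects inverse-variance weighting with and without an LD
    correlation correction, MR-Egger with SIMEX dilution correction, weighted
    median, weighted mode, multivariable MR), heterogeneity, pleiotropy,
    outlier (MR-PRESSO) and leave-one-out diagnostics, sex-stratified
    difference testing with false-discovery-rate control, and a synthetic
    two-sample GWAS generator with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
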