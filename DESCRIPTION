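Package: mrgj
Title: Two-Sample Mendelian Randomization for Microbiome Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    inferring causal effects of gut microbial taxa and microbial metabolic
    pathways on a binary disease outcome from GWAS summary statistics.
    Covers instrument selection (exposure p-value thresholding, greedy LD
    clumping, R-squared/F instrument-strength filtering, confounder-list
    exclusion), exposure-outcome harmonization with palindromic-SNP
    resolution, five causal estimators (inverse-variance weighted, MR-Egger,
    weighted median, simple mode, weighted mode), and a sensitivity suite
    (Cochran's Q heterogeneity, Egger intercept pleiotropy test,
    leave-one-out influence analysis, Steiger directionality test).
    Includes a synthetic two-sample GWAS generator with known ground truth
    so every pipeline stage can be validated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
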