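# mrgj

Two-sample Mendelian randomization (MR) for microbiome exposures and a
binary disease outcome, from GWAS summary statistics only.

## The scientific problem

Observational associations between the gut microbiome and inflammatory
joint disease are confounded by diet, antibiotics, and reverse
causation. Mendelian randomization sidesteps this by using germline
variants as instruments: a SNP that raises the abundance of a microbial
taxon is assigned at conception, before any confounding exposure, so if
taxon-raising alleles also raise disease risk, that supports a causal
effect of the taxon. In the two-sample design the SNP-exposure effects
(from a microbiome GWAS, sample size ~18,000) and the SNP-outcome
effects (from a disease GWAS, ~148,000 participants with ~1,000 cases)
come from different studies, and the analysis needs nothing beyond the
two summary-statistics files.

For each instrument SNP *j* with exposure effect γ̂ⱼ and outcome
log-odds effect Γ̂ⱼ, the Wald ratio θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ estimates the causal
log-odds ratio β. mrgj pools the ratios five ways — inverse-variance
weighted (IVW), MR-Egger, weighted median, simple mode, weighted mode —
whose differing robustness to invalid instruments makes agreement
between them the substantive result. A sensitivity suite (Cochran's Q,
Egger intercept, leave-one-out, Steiger directionality) probes the
instrument assumptions. See `vignette("mr-methods")` for the full model
and estimator details.

The package covers the complete pipeline:

- **`sumstats_io`** — read/validate/write GWAS summary statistics
  (GWAS-SSF-style columns) and LD matrices, with byte-deterministic
  output.
- **`harmonize`** — align outcome to exposure effect alleles, including
  strand flips and frequency-based resolution of palindromic SNPs.
- **`instruments`** — p-value thresholding, greedy LD clumping, R²/F
  instrument strength, weak-instrument and confounder filtering.
- **`estimators`** — the five estimators above plus `mr_all()`.
- **`sensitivity`** — `sensitivity_suite()` and its parts.
- **`simulate`** — a ground-truth synthetic two-sample GWAS generator.
- **`pipeline`** — config-driven screening of many exposures against
  one outcome with TSV/JSON reports.

## Worked example

The package ships a generator for realistic fixture datasets, so the
example is fully self-contained:

```r
library(mrgj)

dir <- file.path(tempdir(), "mrgj-demo")
make_fixture_suite(dir, seed = 42)   # five scenarios with known truth

exposure <- read_sumstats(file.path(dir, "strong_positive", "exposure.tsv"),
                          trait_id = "taxon_abundance")
outcome  <- read_sumstats(file.path(dir, "strong_positive", "outcome.tsv"),
                          trait_id = "disease", trait_type = "binary",
                          n_cases = 1086, n_controls = 147221,
                          allow_missing_eaf = TRUE)
ld <- read_ld_matrix(file.path(dir, "strong_positive", "ld.tsv"))

sel <- select_instruments(exposure, outcome, ld)
sel$filter_log
#>                  stage n_before n_after
#> 1        pvalue_filter       26      26
#> 2             ld_clump       26      13
#> 3            harmonize       13      11
#> 4 confounder_exclusion       11      11
#> 5             f_filter       11      11

mr_all(sel)[, c("method", "nsnp", "pval", "or_ci_text")]
#>            method nsnp         pval       or_ci_text
#> 1             ivw   11 2.638600e-09 1.67 (1.41-1.97)
#> 2     egger_slope   11 1.489234e-01 1.68 (0.80-3.52)
#> 3 weighted_median   11 4.216645e-08 1.74 (1.43-2.12)
#> 4     simple_mode   11 3.284988e-02 1.43 (1.03-1.98)
#> 5   weighted_mode   11 6.877621e-05 1.78 (1.34-2.37)

sens <- sensitivity_suite(sel)
sens$heterogeneity
#>   method        q df      pval
#> 1    ivw 14.61727 10 0.1466511
#> 2  egger 14.61640  9 0.1020263
sens$pleiotropy$verdict
#> [1] "no_horizontal_pleiotropy_detected"
sens$steiger$correct_direction
#> [1] TRUE
```

The scenario's true causal odds ratio is 1.63; IVW and the robust
estimators recover it within sampling error at 11 instruments, the
Egger intercept finds no directional pleiotropy, and Steiger confirms
the exposure-to-outcome orientation.

To screen many exposures against one outcome from a config file, see
`run_config()` / `run_pipeline()` / `render_report()`, which write
`report.tsv`, `forest.tsv`, `leave_one_out.tsv`, `pvalue_matrix.tsv`,
and `run_summary.json`.

## Testing

```sh
NOT_CRAN=true Rscript -e 'testthat::test_dir("tests/testthat", package = "mrgj", load_package = "installed")'
```

The suite includes per-module unit tests with independent oracles
(e.g. IVW against `lm()` weighted least squares, clumping against an
exhaustive reference implementation) and a statistical acceptance file
(`tests/testthat/test-acceptance.R`) that validates parameter recovery,
CI coverage, type-I error, and robustness orderings on simulated data
with known truth.

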