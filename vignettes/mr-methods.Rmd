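---
title: "Methods: two-sample Mendelian randomization in mrgj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrgj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The causal model

mrgj implements two-sample Mendelian randomization (MR) for a continuous
(or log-transformed relative-abundance) exposure $X$ — for example a gut
microbial taxon or a microbial metabolic pathway — and a binary disease
outcome $Y$, using only GWAS summary statistics from two non-overlapping
samples. For each SNP $j$ used as an instrument we observe the estimated
per-allele effect on the exposure, $\hat\gamma_j$ (SE $\sigma_{Xj}$), and
on the outcome on the log-odds scale, $\hat\Gamma_j$ (SE $\sigma_{Yj}$).
Under the instrumental-variable assumptions (relevance, independence from
confounders, and exclusion restriction), each valid SNP identifies the
same causal log-odds ratio $\beta$ through the Wald ratio

$$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j,
  \qquad
  \mathrm{se}(\hat\theta_j) = \sigma_{Yj} / |\hat\gamma_j|,$$

where the SE is the usual first-order approximation that treats
$\hat\gamma_j$ as fixed. This is accurate when instruments are strong
(per-SNP F well above 10, which the selection pipeline enforces) and is
the convention used throughout the package.

# Instrument selection

`select_instruments()` applies, in order:

1. **Exposure p-value threshold** (`p_threshold`, default `1e-5`, strict
   `<`). The conventional genome-wide threshold `5e-8` yields too few
   instruments for microbial traits; `1e-5` is the standard relaxed
   threshold in microbiome MR.
2. **Greedy LD clumping** (`r2_threshold = 0.001`,
   `window_kb = 10000`): repeatedly keep the remaining SNP with the
   smallest exposure p-value (ties broken by chromosome, position,
   variant id) and discard all SNPs within the window on the same
   chromosome with $r^2$ at or above the threshold. This is the standard
   clumping algorithm; mrgj implements it directly against a supplied LD
   matrix rather than shelling out to an external tool, so runs are
   self-contained and reproducible.
3. **Harmonization** (below).
4. **Confounder exclusion**: optional removal of SNPs known to act
   through confounders, by variant id.
5. **Weak-instrument filtering**: per-SNP F must exceed 10 (strict `>`).

The explained variance for SNP $j$ with effect-allele frequency $p_j$
uses the SE-adjusted form when the instrument count $i \ge 10$,

$$R^2_j = \frac{2 p_j (1-p_j)\hat\gamma_j^2}
              {2 p_j (1-p_j)\hat\gamma_j^2 + 2 p_j (1-p_j)\, N\, \sigma_{Xj}^2},$$

and the plain $2 p_j (1-p_j)\hat\gamma_j^2$ otherwise; the F statistic is

$$F = \frac{R^2 (N - 1 - i)}{(1 - R^2)\, i},$$

with $i = 1$ for per-SNP strength and $i$ equal to the instrument count
for the strength of the whole set. Dividing by $i$ (the numerator degrees
of freedom) follows the standard multi-instrument F formula.

# Harmonization

`harmonize()` aligns outcome records to the exposure effect allele.
Non-palindromic pairs are kept as-is, allele-swapped (negating
$\hat\Gamma_j$ and complementing the outcome EAF), strand-flipped, or
both; irreconcilable pairs are dropped as `allele_mismatch`.
Palindromic SNPs (A/T or C/G) cannot be resolved from the allele labels,
so mrgj resolves them purely from allele frequencies: if both EAFs are on
the same side of 0.5 the pair is kept, if on opposite sides it is
treated as swapped, and if either EAF lies within
`palindrome_eaf_margin` (default 0.08) of 0.5 — or the outcome EAF is
missing — the SNP is dropped as `palindromic_ambiguous`. The margin
guards against mis-orientation when sampling noise can move an EAF
across 0.5.

# Estimators

All estimators consume the Wald ratios (equivalently, the harmonized
effect pairs) and return a common `mr_estimate` structure with the
log-OR estimate, SE, 95% CI, p-value, and the OR scale.

**IVW.** The inverse-variance weighted estimate is the weighted mean of
the ratios with weights $w_j = \mathrm{se}(\hat\theta_j)^{-2}$, which is
algebraically identical to weighted least squares of $\hat\Gamma_j$ on
$\hat\gamma_j$ through the origin. The default
`effects_model = "multiplicative_random"` inflates the SE by
$\sqrt{\max(1, Q/(J-1))}$, where $Q$ is Cochran's statistic, so the
estimate is unchanged but the CI widens under heterogeneity; `"fixed"`
reproduces plain WLS.

**MR-Egger.** Weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
with an intercept, weights $\sigma_{Yj}^{-2}$, after orienting all SNPs
so $\hat\gamma_j \ge 0$. The intercept estimates the average directional
pleiotropic effect; the slope is consistent for $\beta$ under the InSIDE
assumption. Inference uses t distributions on $J - 2$ degrees of
freedom, with SEs inflated by $\sqrt{\max(1, Q_E/(J-2))}$.

**Weighted median.** Order the ratios, form the cumulative mid-weights
$s_j = \sum_{k \le j} p_k - p_j/2$ with normalized weights $p_j$, and
linearly interpolate $\hat\theta$ at $s = 0.5$. Consistent when valid
instruments carry at least half the weight. The SE comes from a
parametric bootstrap (default `n_boot = 1000`) resampling
$\theta_j^* \sim N(\hat\theta_j, \mathrm{se}(\hat\theta_j))$ and
re-evaluating the point estimator; the bootstrap seed is an explicit
argument (default `20241126`) so results are reproducible.

**Simple and weighted mode.** The argmax of a normal-kernel density of
the ratios, evaluated on a 512-point grid over
$[\min\theta - 3h, \max\theta + 3h]$ with bandwidth
$h = \phi \cdot 0.9 \cdot \min(\mathrm{sd}, \mathrm{IQR}/1.349) \cdot J^{-1/5}$
(modified Silverman rule; `phi = 1` by default). The weighted variant
weights each kernel by $w_j$. Consistent under ZEMPA (the largest group
of instruments sharing an estimate are the valid ones). SEs by the same
parametric bootstrap.

`mr_all()` runs all five and formats ORs as `"%.2f (%.2f-%.2f)"`, the
conventional table style.

# Sensitivity analyses

`sensitivity_suite()` bundles:

- **Cochran's Q** against the IVW fit ($J-1$ df) and the Egger residual
  $Q_E$ ($J-2$ df), with chi-square p-values.
- **Egger intercept test**: `horizontal_pleiotropy_detected` when the
  intercept p-value is below 0.05.
- **Leave-one-out**: the IVW fit with each SNP excluded in turn
  ($J + 1$ rows including the full fit), flagging exclusions that flip
  the pooled sign (`flag_sign`) or move the p-value across 0.05
  (`flag_p`).
- **Steiger directionality**: compares the variance explained in the
  exposure (summed per-SNP $R^2$) with that explained in the outcome
  ($z^2/(z^2 + n)$ per SNP on the liability-free observed scale), and
  tests the difference with a Fisher z comparison with variance
  $1/(n_X - 3) + 1/(n_Y - 3)$. `correct_direction = TRUE` supports the
  exposure-to-outcome orientation.

# The synthetic GWAS generator

`simulate_pair()` generates a matched exposure/outcome summary-statistic
pair with full ground truth, for validation and worked examples. Per
SNP: $\mathrm{maf} \sim U(0.2, 0.5)$,
$\gamma_j \sim N(0.15, 0.06)$ (defaults), true outcome effect
$\Gamma_j = \beta\gamma_j + \alpha_j$ with optional balanced,
directional, or InSIDE-violating pleiotropy $\alpha_j$, and estimates
drawn with the analytic large-sample SEs

$$\sigma_{Xj} = \big(2p_j(1-p_j)\,n_X\big)^{-1/2}, \qquad
  \sigma_{Yj} = \big(2p_j(1-p_j)\,n_Y\, \phi(1-\phi)\big)^{-1/2},$$

where $\phi$ is the outcome case fraction — the standard approximations
for a standardized continuous trait and a logistic score test. Default
sample sizes ($n_X = 18{,}340$, $n_Y = 148{,}307$, 1,086 cases) mirror
the scale of consortium microbiome GWAS meta-analyses paired with a
biobank disease outcome, and the default $\gamma$ distribution gives
per-SNP F around 200, typical of relaxed-threshold microbiome
instruments. With directional pleiotropy, exactly the first
`round(frac * J)` SNPs carry the direct effect, so the invalid fraction
is a design constant rather than a random variable.

Each SNP is drawn from its own seeded substream, so extending a
simulation with more SNPs never perturbs earlier draws, and every run is
reproducible to the byte. Substream seeds are derived from the run seed
with a splitmix32 integer hash rather than a linear map: R initializes
its generator from the seed with a weak linear scramble, so streams
started from nearby or linearly related seeds are correlated, which
would silently overdisperse replicate averages in simulation studies. The generator emulates: allele swaps, strand
flips, palindromic SNPs, block-diagonal LD, and weak/pleiotropic
instruments. It does **not** emulate: sample overlap between the two
GWAS, EAF estimation noise, population stratification, winner's-curse
selection of instruments, or non-additive genetic effects.

`make_fixture_suite()` writes five small (26-SNP) scenario datasets
(null, strong positive, protective, directional pleiotropy, high
heterogeneity) with a JSON manifest, used by the test suite and the
README example.

# Pipeline and reporting

The screening pipeline is exposed as plain R functions rather than a
shell entry point, so it composes with scripting and testing:
`run_config()` (or `read_run_config()` for YAML/JSON files) validates a
run specification mapping many exposure files to one outcome;
`run_pipeline()` analyses each exposure independently — a malformed
exposure yields an error row without affecting the others — and
`render_report()` writes `report.tsv`, `forest.tsv`,
`leave_one_out.tsv`, `pvalue_matrix.tsv`, and `run_summary.json`.
Significance is the strict unadjusted rule `ivw_p < alpha` (default
0.05), matching common practice in screening studies;
`flag_significant(adjust = TRUE)` adds Benjamini-Hochberg adjusted
p-values for readers who prefer FDR control.

# Numerical conventions

- All file output is written with 17-significant-digit formatting
  through a binary connection, so repeated runs are byte-identical
  across platforms.
- Bootstrap and simulation seeds are explicit arguments, never taken
  from the global RNG state, and the global state is restored after use.
- Generated p-values are floored at `1e-300` to stay inside `(0, 1]`
  in extreme-precision regimes.
- Egger coefficient SEs are computed directly from the weighted normal
  equations and inflated by $\max(1, \hat\sigma)$, which remains finite
  for exactly collinear-free, zero-residual inputs.

# Limitations

- Wald-ratio SEs ignore exposure-side uncertainty; with weak
  instruments this understates variance, and IVW acquires a bias of
  order $\beta\,\sigma_X^2\,\mathrm{E}[1/\gamma^2]$. The F > 10 filter
  bounds, but does not remove, this effect.
- MR-Egger suffers errors-in-variables dilution of order
  $\sigma_X^2 / \mathrm{var}(\gamma)$ (the $I^2_{GX}$ statistic);
  with weakly varying instrument strengths its slope is attenuated.
- Binary-outcome effects are on the log-odds scale from a score test;
  non-collapsibility means the estimand is an approximation to the
  population causal OR.
- Palindromic resolution from EAF assumes both studies draw from
  populations with comparable allele frequencies.
- The bootstrap SEs for median/mode estimators are parametric, not
  resampling-based, and inherit the first-order ratio SEs.

# Typical problem sizes

The package is routinely exercised on 10-50 instruments per exposure
(the realistic range after relaxed-threshold selection and clumping),
exposure sample sizes around 18,000, outcome sample sizes around
150,000 with ~1,000 cases, and screening runs over dozens to hundreds
of exposures. All estimators are closed-form or 512-point-grid
computations; a full five-estimator fit with sensitivity suite takes
milliseconds, and a 500-replicate simulation study runs in about a
minute on one CPU.
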