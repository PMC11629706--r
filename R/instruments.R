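# Instrument selection: exposure p-value threshold, greedy LD clumping,
# R-squared / F instrument-strength computation and weak-instrument removal,
# confounder-list exclusion.

#' Filter candidate variants by exposure p-value
#'
#' Keeps exactly the records with `pval < threshold` (strict), order
#' preserved. An empty result is allowed.
#'
#' @param candidates A [sumstats] object.
#' @param threshold Significance level in (0,1]; the conventional choices are
#'   5e-8 (genome-wide) and 1e-5 (the relaxed threshold used for microbiome
#'   exposures, where genome-wide-significant hits are too few).
#' @return A [sumstats] object containing the surviving subset.
#' @export
filter_by_pvalue <- function(candidates, threshold = 1e-5) {
  stopifnot(inherits(candidates, "sumstats"), threshold > 0, threshold <= 1)
  rec <- candidates$records
  out <- candidates
  out$records <- rec[rec$pval < threshold, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value as an
#' index SNP and removes every other remaining variant on the same chromosome
#' within `window_kb` kilobases whose squared correlation with the index is
#' at least `r2_threshold`. Any two retained SNPs within the window on the
#' same chromosome therefore have `r2 < r2_threshold`. Ties on p-value are
#' broken by (chromosome, position, variant_id), so the result does not
#' depend on input order.
#'
#' @param candidates A [sumstats] object (typically after
#'   [filter_by_pvalue()]).
#' @param ld An [ld_matrix] covering every candidate.
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param window_kb Distance window in kilobases (default 10000).
#' @return A [sumstats] object containing the retained index SNPs, in
#'   selection order.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(candidates, "sumstats"), inherits(ld, "ld_matrix"))
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  rec <- candidates$records
  missing <- setdiff(rec$variant_id, ld$variant_ids)
  if (length(missing) > 0) {
    stop("candidate(s) absent from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(rec) == 0) return(candidates)

  ord <- order(rec$pval, rec$chrom, rec$pos, rec$variant_id)
  rec <- rec[ord, ]
  idx_in_ld <- match(rec$variant_id, ld$variant_ids)
  remaining <- rep(TRUE, nrow(rec))
  chosen <- integer(0)
  window_bp <- window_kb * 1000

  while (any(remaining)) {
    i <- which(remaining)[1]
    chosen <- c(chosen, i)
    remaining[i] <- FALSE
    rem <- which(remaining)
    if (length(rem) == 0) break
    same_chr <- rec$chrom[rem] == rec$chrom[i]
    near <- abs(rec$pos[rem] - rec$pos[i]) <= window_bp
    r2 <- ld$r2[idx_in_ld[i], idx_in_ld[rem]]
    remove <- same_chr & near & (r2 >= r2_threshold)
    remaining[rem[remove]] <- FALSE
  }
  out <- candidates
  out$records <- rec[chosen, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Variance in the exposure explained by one SNP
#'
#' Two forms, switched on the instrument count `i`:
#' \deqn{R^2 = 2\,EAF(1-EAF)\beta^2 \quad (i < 10)}
#' \deqn{R^2 = \frac{2\,EAF(1-EAF)\beta^2}
#'   {2\,EAF(1-EAF)\beta^2 + 2\,EAF(1-EAF)\,N\,SE^2} \quad (i \ge 10)}
#' The second form is bounded in `[0,1)`; the first assumes a standardized
#' trait and per-allele effects.
#'
#' @param eaf Effect-allele frequency, strictly inside (0,1).
#' @param beta Per-allele effect size.
#' @param se Standard error of `beta` (needed for the `i >= 10` form).
#' @param n Sample size (needed for the `i >= 10` form).
#' @param variant_count Number of effective instruments `i` in the set the
#'   SNP belongs to (1 for per-SNP strength assessment).
#' @return R-squared value(s); vectorized over the association arguments.
#' @export
snp_r2 <- function(eaf, beta, se = NULL, n = NULL, variant_count = 1) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("degenerate EAF: must lie strictly inside (0,1)", call. = FALSE)
  }
  v <- 2 * eaf * (1 - eaf)
  if (variant_count < 10) {
    return(v * beta^2)
  }
  if (is.null(se) || is.null(n)) {
    stop("se and n are required for the i >= 10 form", call. = FALSE)
  }
  num <- v * beta^2
  num / (num + v * n * se^2)
}

#' Instrument-strength F statistic
#'
#' \deqn{F = \frac{R^2 (N - 1 - i)}{(1 - R^2)\, i}}
#' the usual F statistic for `i` regressors jointly explaining `R^2` of a
#' trait in a sample of size `N`. `F > 10` is the conventional
#' weak-instrument cutoff.
#'
#' @param r2 Variance explained, in `[0,1)`.
#' @param n Sample size; must exceed `i + 1`.
#' @param i Number of instruments (default 1).
#' @return F value(s); vectorized.
#' @export
f_statistic <- function(r2, n, i = 1) {
  if (any(r2 < 0 | r2 >= 1)) stop("domain error: r2 must be in [0,1)", call. = FALSE)
  if (any(n <= i + 1)) stop("domain error: n must exceed i + 1", call. = FALSE)
  if (any(i < 1)) stop("domain error: i must be at least 1", call. = FALSE)
  r2 * (n - 1 - i) / ((1 - r2) * i)
}

.per_snp_strength <- function(inst) {
  # Per-SNP strength uses i = 1 and hence the simple R^2 form.
  r2 <- snp_r2(inst$eaf_exp, inst$beta_exp, inst$se_exp, inst$n_exp,
               variant_count = 1)
  f <- f_statistic(r2, inst$n_exp, i = 1)
  data.frame(variant_id = inst$variant_id, r2_snp = r2, f_snp = f,
             stringsAsFactors = FALSE)
}

.set_strength <- function(inst) {
  i <- nrow(inst)
  if (i == 0) return(list(r2_total = 0, f_total = NA_real_, i = 0L))
  r2_total <- sum(snp_r2(inst$eaf_exp, inst$beta_exp, inst$se_exp,
                         inst$n_exp, variant_count = i))
  n <- stats::median(inst$n_exp)
  f_total <- if (r2_total < 1 && n > i + 1) f_statistic(r2_total, n, i) else NA_real_
  list(r2_total = r2_total, f_total = f_total, i = as.integer(i))
}

#' Remove weak instruments by per-SNP F statistic
#'
#' Computes each instrument's strength with `i = 1` (single-regressor form)
#' and keeps only SNPs with `F > f_threshold` (strict). Set-level R-squared
#' and F are recomputed on the survivors, using the SE-adjusted R-squared
#' form when the surviving set has at least 10 SNPs.
#'
#' @param h A `harmonized_set` (from [harmonize()]).
#' @param f_threshold Minimum F (default 10).
#' @return Object of class `instrument_set`: list with `instruments` (the
#'   surviving harmonized rows), `dropped` (variant_id, reason),
#'   `per_snp_strength` (variant_id, r2_snp, f_snp for all inputs),
#'   `set_strength` (r2_total, f_total, i) and `filter_log`.
#' @export
filter_weak_instruments <- function(h, f_threshold = 10) {
  stopifnot(inherits(h, "harmonized_set") || is.data.frame(h))
  inst <- if (is.data.frame(h)) h else h$instruments
  strength <- .per_snp_strength(inst)
  keep <- strength$f_snp > f_threshold
  dropped <- data.frame(
    variant_id = inst$variant_id[!keep],
    reason = sprintf("weak_instrument (F = %.3g <= %g)",
                     strength$f_snp[!keep], f_threshold),
    stringsAsFactors = FALSE
  )
  surv <- inst[keep, , drop = FALSE]
  rownames(surv) <- NULL
  structure(
    list(
      instruments = surv,
      dropped = dropped,
      per_snp_strength = strength,
      set_strength = .set_strength(surv),
      filter_log = data.frame(stage = "f_filter",
                              n_before = nrow(inst), n_after = nrow(surv),
                              stringsAsFactors = FALSE)
    ),
    class = "instrument_set"
  )
}

#' Remove SNPs on a confounder exclusion list
#'
#' Supports the manual confounder-review step of instrument curation: SNPs a
#' phenome scan or literature review ties to confounders of the
#' exposure-outcome pair are excluded by identifier. An empty list is the
#' identity; identifiers absent from the candidates are ignored with a
#' warning.
#'
#' @param s A [sumstats] or `harmonized_set` object.
#' @param exclusion_list Character vector of variant identifiers.
#' @return The same class of object with the listed SNPs removed; the
#'   removals are appended to `dropped` (harmonized sets) with reason
#'   `"confounder_exclusion"`.
#' @export
exclude_confounder_snps <- function(s, exclusion_list = character()) {
  exclusion_list <- as.character(exclusion_list)
  if (length(exclusion_list) == 0) return(s)
  if (inherits(s, "sumstats")) {
    present <- s$records$variant_id %in% exclusion_list
    absent <- setdiff(exclusion_list, s$records$variant_id)
    if (length(absent) > 0) {
      warning("exclusion ids not present: ", paste(absent, collapse = ", "))
    }
    s$records <- s$records[!present, , drop = FALSE]
    rownames(s$records) <- NULL
    return(s)
  }
  if (inherits(s, "harmonized_set")) {
    present <- s$instruments$variant_id %in% exclusion_list
    absent <- setdiff(exclusion_list, s$instruments$variant_id)
    if (length(absent) > 0) {
      warning("exclusion ids not present: ", paste(absent, collapse = ", "))
    }
    s$dropped <- rbind(s$dropped, data.frame(
      variant_id = s$instruments$variant_id[present],
      reason = "confounder_exclusion", stringsAsFactors = FALSE))
    s$instruments <- s$instruments[!present, , drop = FALSE]
    rownames(s$instruments) <- NULL
    return(s)
  }
  stop("unsupported input class", call. = FALSE)
}

#' Full instrument-selection pipeline for one exposure
#'
#' Applies the selection stages in order: exposure p-value filter, LD
#' clumping, harmonization against the outcome, confounder-list exclusion,
#' and per-SNP F filtering. Every stage's before/after counts are recorded.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param ld An [ld_matrix] covering the clumping candidates.
#' @param pval_threshold Exposure significance threshold (default 1e-5).
#' @param clump_r2,clump_kb Clumping parameters (defaults 0.001 and 10000).
#' @param f_threshold Weak-instrument F cutoff (default 10).
#' @param exclusion_list Confounder SNP identifiers to remove.
#' @param palindrome_eaf_margin Passed to [harmonize()].
#' @return An `instrument_set` with a complete `filter_log`.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               pval_threshold = 1e-5,
                               clump_r2 = 0.001, clump_kb = 10000,
                               f_threshold = 10,
                               exclusion_list = character(),
                               palindrome_eaf_margin = 0.08) {
  log_rows <- list()
  note <- function(stage, before, after) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage, n_before = before, n_after = after,
      stringsAsFactors = FALSE)
  }
  n0 <- nrow(exposure$records)
  sig <- filter_by_pvalue(exposure, pval_threshold)
  note("pvalue_filter", n0, nrow(sig$records))
  clumped <- clump(sig, ld, clump_r2, clump_kb)
  note("ld_clump", nrow(sig$records), nrow(clumped$records))
  h <- harmonize(clumped, outcome, palindrome_eaf_margin)
  note("harmonize", nrow(clumped$records), nrow(h$instruments))
  n_pre <- nrow(h$instruments)
  h <- exclude_confounder_snps(h, exclusion_list)
  note("confounder_exclusion", n_pre, nrow(h$instruments))
  iset <- filter_weak_instruments(h, f_threshold)
  note("f_filter", nrow(h$instruments), nrow(iset$instruments))
  iset$filter_log <- do.call(rbind, log_rows)
  iset$dropped <- rbind(h$dropped, iset$dropped)
  iset
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instruments (set R2 = %.4g, F = %.4g)\n",
              x$set_strength$i, x$set_strength$r2_total,
              x$set_strength$f_total))
  if (!is.null(x$filter_log)) {
    print(x$filter_log, row.names = FALSE)
  }
  invisible(x)
}
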