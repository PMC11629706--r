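# Diagnostics: Cochran's Q heterogeneity, Egger intercept pleiotropy verdict,
# leave-one-out influence analysis, Steiger directionality test.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - beta_pooled)^2`, referred to a chi-square
#' distribution. For the IVW pooled estimate the degrees of freedom are
#' `J - 1`; for the Egger fit (which spends one more parameter on the
#' intercept) they are `J - 2`, in which case `pooled` should be the Egger
#' residual statistic (see [heterogeneity()], which assembles both rows).
#' A p-value above 0.05 is conventionally read as no material heterogeneity.
#'
#' @param ratios A `wald_ratios` data frame (>= 2 rows).
#' @param pooled Pooled causal estimate (an `mr_estimate` or a number).
#' @param method `"ivw"` (default) or `"egger"` (affects df only; for the
#'   Egger row prefer [heterogeneity()], which uses the fit's own residuals).
#' @return List of class `heterogeneity_result`: `method, q, df, pval`.
#' @export
cochran_q <- function(ratios, pooled, method = c("ivw", "egger")) {
  method <- match.arg(method)
  J <- nrow(ratios)
  if (J < 2) stop("Cochran's Q requires at least 2 ratios", call. = FALSE)
  beta <- if (inherits(pooled, "mr_estimate")) pooled$beta else as.numeric(pooled)
  q <- sum(ratios$weight * (ratios$theta - beta)^2)
  df <- if (method == "ivw") J - 1 else J - 2
  structure(
    list(method = method, q = q, df = df,
         pval = stats::pchisq(q, df, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' Heterogeneity table (IVW and Egger rows)
#'
#' @param h A `harmonized_set` or `instrument_set`.
#' @param effects_model IVW effects model.
#' @return Data frame with columns `method, q, df, pval`, one row for the
#'   IVW fixed-slope residuals (df `J - 1`) and one for the Egger residuals
#'   (df `J - 2`).
#' @export
heterogeneity <- function(h, effects_model = "multiplicative_random") {
  ratios <- wald_ratios(h)
  ivw <- mr_ivw(ratios, effects_model)
  q_ivw <- cochran_q(ratios, ivw, "ivw")
  eg <- mr_egger(h)
  data.frame(
    method = c("ivw", "egger"),
    q = c(q_ivw$q, eg$q),
    df = c(q_ivw$df, eg$q_df),
    pval = c(q_ivw$pval, stats::pchisq(eg$q, eg$q_df, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Horizontal-pleiotropy verdict from the Egger intercept
#'
#' Reports `"no_horizontal_pleiotropy_detected"` iff the intercept p-value
#' exceeds `alpha` (default 0.05), else
#' `"horizontal_pleiotropy_detected"`. The intercept, its SE and p-value are
#' always carried along: a non-significant intercept is absence of evidence,
#' not evidence of absence.
#'
#' @param egger_fit Either an `mr_egger` object or its `intercept` triple
#'   (list with `estimate`, `se`, `pval`).
#' @param alpha Verdict threshold (default 0.05).
#' @return List `(verdict, estimate, se, pval, alpha)`.
#' @export
egger_intercept_test <- function(egger_fit, alpha = 0.05) {
  ic <- if (inherits(egger_fit, "mr_egger")) egger_fit$intercept else egger_fit
  verdict <- if (ic$pval > alpha) {
    "no_horizontal_pleiotropy_detected"
  } else {
    "horizontal_pleiotropy_detected"
  }
  list(verdict = verdict, estimate = ic$estimate, se = ic$se,
       pval = ic$pval, alpha = alpha)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate once per instrument with that instrument
#' removed, plus the all-SNP row. An instrument is flagged influential when
#' its exclusion flips the sign of the pooled estimate (`flag_sign`) or moves
#' the p-value across 0.05 (`flag_p`); both triggers are reported separately.
#'
#' @param h A `harmonized_set` or `instrument_set` (>= 3 instruments).
#' @param effects_model IVW effects model.
#' @param alpha Significance level for the p-crossing flag.
#' @return Data frame of class `leave_one_out` with `nsnp + 1` rows:
#'   `excluded_variant_id` (`"none"` for the all-SNP row), `beta, se, pval,
#'   flag_sign, flag_p`.
#' @export
leave_one_out <- function(h, effects_model = "multiplicative_random",
                          alpha = 0.05) {
  ratios <- wald_ratios(h)
  J <- nrow(ratios)
  if (J < 3) stop("leave-one-out requires at least 3 instruments", call. = FALSE)
  full <- mr_ivw(ratios, effects_model)
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(ratios[-j, , drop = FALSE], effects_model)
    data.frame(excluded_variant_id = ratios$variant_id[j],
               beta = fit$beta, se = fit$se, pval = fit$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag_sign <- sign(out$beta) != sign(full$beta)
  out$flag_p <- (out$pval < alpha) != (full$pval < alpha)
  out <- rbind(out, data.frame(
    excluded_variant_id = "none", beta = full$beta, se = full$se,
    pval = full$pval, flag_sign = FALSE, flag_p = FALSE,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("leave_one_out", "data.frame")
  out
}

#' Steiger directionality test
#'
#' Guards against reverse causation by comparing the variance the instruments
#' explain in the exposure with the variance they explain in the outcome.
#' Exposure-side R-squared sums the per-SNP `2 EAF (1-EAF) beta^2` values
#' (SE-adjusted form when the set has >= 10 instruments); outcome-side
#' R-squared for the (binary) outcome uses the observed-scale approximation
#' `z^2 / (z^2 + n)` per SNP, which needs no outcome EAF. The inferred
#' direction is correct when `r2_exposure > r2_outcome`; the p-value is a
#' two-sided z test on the difference of Fisher-transformed `sqrt(R2)` values
#' with variance `1/(n_exp - 3) + 1/(n_out - 3)`.
#'
#' @param h A `harmonized_set` or `instrument_set`.
#' @param n_exp,n_out Study sample sizes; default to the per-record medians.
#' @return List of class `steiger_result`: `r2_exposure, r2_outcome,
#'   correct_direction, pval, n_exp, n_out`.
#' @export
steiger_test <- function(h, n_exp = NULL, n_out = NULL) {
  inst <- if (is.data.frame(h)) h else h$instruments
  if (is.null(n_exp)) n_exp <- stats::median(inst$n_exp)
  if (is.null(n_out)) n_out <- stats::median(inst$n_out)
  if (n_exp <= 3 || n_out <= 3) {
    stop("sample sizes must exceed 3 on both sides", call. = FALSE)
  }
  if (anyNA(inst$eaf_exp)) {
    stop("exposure EAF required for the Steiger test", call. = FALSE)
  }
  J <- nrow(inst)
  r2_exp <- sum(snp_r2(inst$eaf_exp, inst$beta_exp, inst$se_exp, inst$n_exp,
                       variant_count = J))
  z_out <- inst$beta_out / inst$se_out
  r2_out <- sum(z_out^2 / (z_out^2 + inst$n_out))
  r2_exp <- min(r2_exp, 1 - 1e-12)
  r2_out <- min(r2_out, 1 - 1e-12)
  z_stat <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(
    list(r2_exposure = r2_exp, r2_outcome = r2_out,
         correct_direction = r2_exp > r2_out,
         pval = 2 * stats::pnorm(-abs(z_stat)),
         n_exp = n_exp, n_out = n_out),
    class = "steiger_result"
  )
}

#' Full sensitivity suite
#'
#' Convenience wrapper assembling the heterogeneity table, the Egger
#' intercept verdict, the leave-one-out table, and the Steiger test.
#'
#' @inheritParams leave_one_out
#' @inheritParams steiger_test
#' @return List `(heterogeneity, pleiotropy, loo, steiger)`.
#' @export
sensitivity_suite <- function(h, effects_model = "multiplicative_random",
                              n_exp = NULL, n_out = NULL, alpha = 0.05) {
  list(
    heterogeneity = heterogeneity(h, effects_model),
    pleiotropy = egger_intercept_test(mr_egger(h), alpha),
    loo = leave_one_out(h, effects_model, alpha),
    steiger = steiger_test(h, n_exp, n_out)
  )
}
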