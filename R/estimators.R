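# Causal estimators for two-sample MR from harmonized instruments:
# IVW (primary), MR-Egger, weighted median, simple mode, weighted mode.

# Run code under a temporary RNG state without disturbing the caller's.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Per-SNP Wald ratios
#'
#' The per-SNP causal estimate `theta_j = beta_out_j / beta_exp_j` with the
#' first-order standard error `se_theta_j = se_out_j / |beta_exp_j|` and
#' inverse-variance weight `se_theta_j^-2`. SNPs with a zero exposure effect
#' are excluded and reported in the `"excluded"` attribute.
#'
#' @param h A `harmonized_set`, `instrument_set`, or a data frame with
#'   columns `variant_id, beta_exp, se_exp, beta_out, se_out`.
#' @return Data frame `(variant_id, theta, se_theta, weight)` of class
#'   `wald_ratios`.
#' @export
wald_ratios <- function(h) {
  inst <- if (is.data.frame(h)) h else h$instruments
  zero <- inst$beta_exp == 0
  excluded <- inst$variant_id[zero]
  inst <- inst[!zero, , drop = FALSE]
  out <- data.frame(
    variant_id = inst$variant_id,
    theta = inst$beta_out / inst$beta_exp,
    se_theta = inst$se_out / abs(inst$beta_exp),
    stringsAsFactors = FALSE
  )
  out$weight <- out$se_theta^-2
  attr(out, "excluded") <- excluded
  class(out) <- c("wald_ratios", "data.frame")
  out
}

.mr_estimate <- function(method, nsnp, beta, se, pval,
                         ci_low = beta - stats::qnorm(0.975) * se,
                         ci_high = beta + stats::qnorm(0.975) * se,
                         extra = list()) {
  est <- c(list(
    method = method, nsnp = as.integer(nsnp), beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval,
    or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high)
  ), extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: nsnp=%d beta=%.4g se=%.4g p=%.3g OR %s\n",
              x$method, x$nsnp, x$beta, x$se, x$pval,
              format_or_ci(x$or, x$or_ci_low, x$or_ci_high)))
  invisible(x)
}

#' Normal-theory summary of an estimate
#'
#' 95% confidence bounds `beta -/+ 1.959964 se`, the two-sided normal
#' p-value, and all three quantities exponentiated to the odds-ratio scale.
#'
#' @param beta Point estimate on the log-odds scale.
#' @param se Standard error (positive).
#' @return List with `ci_low`, `ci_high`, `pval`, and `or_scale`
#'   `(or, or_ci_low, or_ci_high)`.
#' @export
wald_summary <- function(beta, se) {
  stopifnot(se > 0)
  z <- stats::qnorm(0.975)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  pval <- 2 * stats::pnorm(-abs(beta) / se)
  list(ci_low = ci_low, ci_high = ci_high, pval = pval,
       or_scale = c(or = exp(beta), or_ci_low = exp(ci_low),
                    or_ci_high = exp(ci_high)))
}

#' Inverse-variance-weighted estimator
#'
#' The weighted mean of the Wald ratios, `sum(w theta) / sum(w)` with
#' `w = se_theta^-2`; identical to weighted least squares of `beta_out` on
#' `beta_exp` through the origin with weights `se_out^-2`. Under the
#' (default) multiplicative random-effects model the fixed-effects standard
#' error `(sum w)^-1/2` is inflated by `sqrt(max(1, Q/(J-1)))`, with Q
#' Cochran's heterogeneity statistic, so heterogeneity widens but never
#' narrows the interval. P-values are standard normal.
#'
#' @param ratios A `wald_ratios` data frame (see [wald_ratios()]).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate`; a single ratio degenerates to the Wald estimate
#'   with a warning.
#' @export
mr_ivw <- function(ratios, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  J <- nrow(ratios)
  if (J == 0) stop("no Wald ratios supplied", call. = FALSE)
  if (J == 1) warning("single instrument: IVW degenerates to the Wald estimate")
  w <- ratios$weight
  beta <- sum(w * ratios$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (ratios$theta - beta)^2)
  if (effects_model == "multiplicative_random" && J > 1) {
    se <- se * sqrt(max(1, q / (J - 1)))
  }
  ws <- wald_summary(beta, se)
  .mr_estimate("ivw", J, beta, se, ws$pval, ws$ci_low, ws$ci_high,
               extra = list(effects_model = effects_model, q = q,
                            q_df = J - 1))
}

# Weighted linear fit of beta_out on beta_exp with intercept, instruments
# oriented so beta_exp >= 0. Returns coefficients, SEs adjusted by
# sqrt(max(1, Q_E/(J-2))), and the Egger heterogeneity statistic.
.egger_fit <- function(inst) {
  flip <- sign(inst$beta_exp)
  flip[flip == 0] <- 1
  x <- inst$beta_exp * flip
  y <- inst$beta_out * flip
  w <- inst$se_out^-2
  if (stats::var(x) == 0) {
    stop("collinearity: all exposure effects identical after orientation",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x, weights = w)
  J <- length(x)
  sigma <- summary(fit)$sigma  # sqrt(Q_E / (J - 2)) under weights se_out^-2
  est <- unname(stats::coef(fit))
  # Fixed-effect SEs from the weighted normal equations, scaled up (never
  # down) under residual heterogeneity.
  X <- cbind(1, x)
  se_fixed <- unname(sqrt(diag(solve(crossprod(X, w * X)))))
  se <- se_fixed * max(1, sigma)
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = J - 2)
  q_e <- sigma^2 * (J - 2)
  list(intercept = est[1], slope = est[2],
       se_intercept = se[1], se_slope = se[2],
       pval_intercept = pval[1], pval_slope = pval[2],
       q = q_e, q_df = J - 2, nsnp = J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with an intercept, each instrument oriented so its exposure effect is
#' non-negative and weighted by `se_out^-2`. The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates the average
#' directional pleiotropic effect, and its test (p > 0.05 consistent with no
#' horizontal pleiotropy) is the standard pleiotropy diagnostic. Standard
#' errors are inflated by `sqrt(max(1, Q_E/(J-2)))`; p-values use the t
#' distribution with `J - 2` degrees of freedom (small-J intercept inference
#' is the test's known fragility).
#'
#' @param h A `harmonized_set`, `instrument_set`, or data frame with columns
#'   `beta_exp, se_exp, beta_out, se_out` (at least 3 instruments).
#' @return List of class `mr_egger` with `slope` (an `mr_estimate`) and
#'   `intercept` (list `estimate, se, pval`), plus `q`/`q_df`.
#' @export
mr_egger <- function(h) {
  inst <- if (is.data.frame(h)) h else h$instruments
  if (nrow(inst) < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  f <- .egger_fit(inst)
  tq <- stats::qt(0.975, df = f$q_df)
  slope <- .mr_estimate(
    "egger_slope", f$nsnp, f$slope, f$se_slope, f$pval_slope,
    ci_low = f$slope - tq * f$se_slope,
    ci_high = f$slope + tq * f$se_slope,
    extra = list(q = f$q, q_df = f$q_df)
  )
  structure(
    list(slope = slope,
         intercept = list(estimate = unname(f$intercept),
                          se = unname(f$se_intercept),
                          pval = unname(f$pval_intercept)),
         q = f$q, q_df = f$q_df, nsnp = f$nsnp),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g (se %.4g, p %.3g)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pval))
  invisible(x)
}

# Weighted-median point estimate: sort theta, cumulative mid-weights
# s_j = cumsum(p)_j - p_j/2, linear interpolation at s = 0.5.
.weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

.boot_se <- function(theta, se_theta, w, point_fn, n_boot, seed) {
  .with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      point_fn(stats::rnorm(length(theta), theta, se_theta), w)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The median of the Wald-ratio distribution weighted by inverse variance:
#' consistent when valid instruments carry more than half the total weight,
#' hence robust to up to 50% invalid weight. The standard error comes from a
#' parametric bootstrap: each ratio is resampled from
#' `N(theta_j, se_theta_j)` and the estimator recomputed.
#'
#' @param ratios A `wald_ratios` data frame (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 1000; fewer than 100 warns,
#'   fewer than 2 errors).
#' @param seed RNG seed for the bootstrap (recorded in the output).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = 20241126) {
  J <- nrow(ratios)
  if (J < 3) stop("weighted median requires at least 3 ratios", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")
  beta <- .weighted_median_point(ratios$theta, ratios$weight)
  se <- .boot_se(ratios$theta, ratios$se_theta, ratios$weight,
                 .weighted_median_point, n_boot, seed)
  ws <- wald_summary(beta, se)
  .mr_estimate("weighted_median", J, beta, se, ws$pval, ws$ci_low, ws$ci_high,
               extra = list(n_boot = n_boot, seed = seed))
}

.mode_point <- function(theta, w, phi = 1) {
  s <- stats::sd(theta)
  iqr <- stats::IQR(theta)
  h <- phi * 0.9 * min(s, iqr / 1.349) * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512)
  wn <- w / sum(w)
  dens <- vapply(grid, function(g) sum(wn * stats::dnorm(g, theta, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The argmax of a normal-kernel-smoothed density of the Wald ratios,
#' evaluated on a 512-point grid spanning `[min(theta) - 3h, max(theta) + 3h]`
#' with bandwidth `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`. The simple
#' mode weights all ratios equally; the weighted mode weights them by inverse
#' variance. Consistent when the largest group of instruments sharing a
#' causal estimate are the valid ones (ZEMPA). Standard errors by parametric
#' bootstrap as in [mr_weighted_median()].
#'
#' @param ratios A `wald_ratios` data frame (>= 3 rows).
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform weights.
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param n_boot,seed Bootstrap settings as in [mr_weighted_median()].
#' @return An `mr_estimate` (method `"weighted_mode"` or `"simple_mode"`). If
#'   all ratios are identical the common value is returned with `se = 0` and
#'   a warning.
#' @export
mr_mode <- function(ratios, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = 20241126) {
  J <- nrow(ratios)
  if (J < 3) stop("mode estimator requires at least 3 ratios", call. = FALSE)
  stopifnot(phi > 0)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  w <- if (weighted) ratios$weight else rep(1, J)
  if (stats::sd(ratios$theta) == 0) {
    warning("all Wald ratios identical: zero bandwidth, returning common value")
    beta <- ratios$theta[1]
    return(.mr_estimate(method, J, beta, 0, 1, beta, beta,
                        extra = list(phi = phi, n_boot = n_boot, seed = seed)))
  }
  point <- function(th, ww) .mode_point(th, ww, phi)
  beta <- point(ratios$theta, w)
  se <- .boot_se(ratios$theta, ratios$se_theta, w, point, n_boot, seed)
  ws <- wald_summary(beta, se)
  .mr_estimate(method, J, beta, se, ws$pval, ws$ci_low, ws$ci_high,
               extra = list(phi = phi, n_boot = n_boot, seed = seed))
}

#' Fit all requested MR estimators
#'
#' @param h A `harmonized_set` or `instrument_set`.
#' @param methods Subset of
#'   `c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")`.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param n_boot,seed Bootstrap settings for median/mode estimators.
#' @return Data frame with one row per method: `method, nsnp, beta, se,
#'   ci_low, ci_high, pval, or, or_ci_low, or_ci_high, or_ci_text`.
#' @export
mr_all <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"),
                   effects_model = "multiplicative_random",
                   n_boot = 1000, seed = 20241126) {
  methods <- match.arg(methods, several.ok = TRUE)
  ratios <- wald_ratios(h)
  ests <- list()
  for (m in methods) {
    ests[[m]] <- switch(
      m,
      ivw = mr_ivw(ratios, effects_model),
      egger = mr_egger(h)$slope,
      weighted_median = mr_weighted_median(ratios, n_boot, seed),
      simple_mode = mr_mode(ratios, weighted = FALSE, n_boot = n_boot, seed = seed),
      weighted_mode = mr_mode(ratios, weighted = TRUE, n_boot = n_boot, seed = seed)
    )
  }
  do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               or = e$or, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
               or_ci_text = format_or_ci(e$or, e$or_ci_low, e$or_ci_high),
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Format an odds ratio with its 95% interval
#'
#' @param or,lo,hi Odds ratio and interval bounds.
#' @return String `"x.xx (x.xx-x.xx)"`.
#' @export
format_or_ci <- function(or, lo, hi) {
  sprintf("%.2f (%.2f-%.2f)", or, lo, hi)
}
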