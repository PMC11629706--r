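test_that("Wald ratios follow first-order arithmetic", {
  inst <- make_instruments(beta_exp = c(0.5, 0.2, -0.3),
                           beta_out = c(0.25, 0, 0.15),
                           se_out = 0.1)
  r <- wald_ratios(inst)
  expect_equal(r$theta, c(0.5, 0, -0.5))
  expect_equal(r$se_theta, c(0.2, 0.5, 1 / 3))
  expect_equal(r$weight, r$se_theta^-2)

  # joint sign flip leaves theta unchanged
  inst2 <- inst
  inst2$beta_exp <- -inst2$beta_exp
  inst2$beta_out <- -inst2$beta_out
  expect_equal(wald_ratios(inst2)$theta, r$theta)

  # zero exposure effect is excluded, not propagated
  inst3 <- make_instruments(beta_exp = c(0, 0.2), beta_out = c(0.1, 0.1))
  r3 <- wald_ratios(inst3)
  expect_equal(nrow(r3), 1)
  expect_equal(attr(r3, "excluded"), "rs1")
})

test_that("IVW reduces to the single Wald ratio and to the equal-weight mean", {
  one <- make_ratios(0.37, 0.1)
  expect_warning(est <- mr_ivw(one), "single instrument")
  expect_equal(est$beta, 0.37)
  expect_equal(est$se, 0.1)

  two <- make_ratios(c(0.2, 0.4), 0.1)
  expect_equal(mr_ivw(two)$beta, 0.3)
  expect_error(mr_ivw(two[0, ]), "no Wald ratios")
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(5)
  for (rep in 1:20) {
    J <- sample(3:30, 1)
    inst <- make_instruments(beta_exp = rnorm(J, 0.2, 0.1) + 0.05,
                             beta_out = rnorm(J, 0.1, 0.2),
                             se_out = abs(rnorm(J, 0.05, 0.02)) + 0.01)
    inst$se_out <- abs(rnorm(J, 0.05, 0.02)) + 0.01
    r <- wald_ratios(inst)
    est <- mr_ivw(r, effects_model = "fixed")
    wls <- lm(beta_out ~ 0 + beta_exp, data = inst, weights = inst$se_out^-2)
    expect_equal(est$beta, unname(coef(wls)), tolerance = 1e-10)
    # fixed-effects SE equals the WLS coefficient SE de-scaled by sigma
    sm <- summary(wls)
    expect_equal(est$se, unname(sm$coefficients[1, 2] / sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("the multiplicative random-effects SE inflates by sqrt(max(1, Q/(J-1)))", {
  r <- make_ratios(c(0.1, 0.5, 0.9, -0.2), 0.05)
  fixed <- mr_ivw(r, "fixed")
  rand <- mr_ivw(r, "multiplicative_random")
  q <- sum(r$weight * (r$theta - fixed$beta)^2)
  expect_equal(rand$se, fixed$se * sqrt(max(1, q / 3)))
  expect_equal(rand$q, q)

  # homogeneous ratios: no deflation below the fixed-effects SE
  hom <- make_ratios(rep(0.3, 6) + c(-1, 1, -1, 1, -1, 1) * 1e-6, 0.05)
  expect_gte(mr_ivw(hom)$se, mr_ivw(hom, "fixed")$se)
})

test_that("MR-Egger recovers exact linear data to machine precision", {
  beta_exp <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  inst <- make_instruments(beta_exp = beta_exp,
                           beta_out = 0.05 + 0.8 * beta_exp,
                           se_out = 0.05)
  fit <- mr_egger(inst)
  expect_equal(fit$intercept$estimate, 0.05, tolerance = 1e-12)
  expect_equal(fit$slope$beta, 0.8, tolerance = 1e-12)
  expect_equal(fit$q, 0, tolerance = 1e-20)
})

test_that("MR-Egger agrees with an independent normal-equations solve", {
  set.seed(11)
  for (rep in 1:10) {
    J <- sample(5:40, 1)
    inst <- make_instruments(beta_exp = abs(rnorm(J, 0.15, 0.06)),
                             beta_out = rnorm(J, 0.05, 0.1),
                             se_out = abs(rnorm(J, 0.05, 0.02)) + 0.01)
    fit <- mr_egger(inst)
    # oracle: weighted normal equations solved generically
    w <- inst$se_out^-2
    X <- cbind(1, inst$beta_exp)
    y <- inst$beta_out
    ab <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    expect_equal(fit$intercept$estimate, ab[1], tolerance = 1e-10)
    expect_equal(fit$slope$beta, ab[2], tolerance = 1e-10)
    resid <- y - X %*% ab
    q_e <- sum(w * resid^2)
    expect_equal(fit$q, q_e, tolerance = 1e-8)
    cov_fixed <- solve(t(X) %*% (w * X))
    infl <- max(1, sqrt(q_e / (J - 2)))
    expect_equal(fit$slope$se, sqrt(cov_fixed[2, 2]) * infl, tolerance = 1e-10)
  }
})

test_that("MR-Egger orients instruments and rejects collinear input", {
  # orientation: re-polarizing any subset of SNPs leaves the fit unchanged
  set.seed(3)
  inst <- make_instruments(beta_exp = abs(rnorm(10, 0.15, 0.06)),
                           beta_out = rnorm(10, 0.05, 0.1), se_out = 0.05)
  flip <- c(1, 3, 8)
  inst2 <- inst
  inst2$beta_exp[flip] <- -inst2$beta_exp[flip]
  inst2$beta_out[flip] <- -inst2$beta_out[flip]
  f1 <- mr_egger(inst)
  f2 <- mr_egger(inst2)
  expect_equal(f2$slope$beta, f1$slope$beta, tolerance = 1e-12)
  expect_equal(f2$intercept$estimate, f1$intercept$estimate, tolerance = 1e-12)

  coll <- make_instruments(beta_exp = rep(0.1, 4), beta_out = rnorm(4))
  expect_error(mr_egger(coll), "collinearity")
  expect_error(mr_egger(inst[1:2, ]), "at least 3")
})

test_that("the weighted median interpolates the cumulative mid-weights", {
  expect_equal(mr_weighted_median(make_ratios(c(1, 2, 3), 0.1),
                                  n_boot = 200, seed = 1)$beta, 2)
  expect_equal(mr_weighted_median(make_ratios(c(1, 2, 3, 4), 0.1),
                                  n_boot = 200, seed = 1)$beta, 2.5)
  # order of input must not matter
  expect_equal(mr_weighted_median(make_ratios(c(4, 1, 3, 2), 0.1),
                                  n_boot = 200, seed = 1)$beta, 2.5)

  # a ratio with > 50% of the weight anchors the estimate near its theta
  r <- make_ratios(c(0.2, 0.9, 1.5), c(0.05, 0.5, 0.5))
  est <- mr_weighted_median(r, n_boot = 200, seed = 1)
  expect_lt(abs(est$beta - 0.2), 0.4)

  expect_error(mr_weighted_median(make_ratios(c(1, 2), 0.1)), "at least 3")
  expect_error(mr_weighted_median(make_ratios(c(1, 2, 3), 0.1), n_boot = 1),
               "at least 2")
  expect_warning(mr_weighted_median(make_ratios(c(1, 2, 3), 0.1), n_boot = 50),
                 "unstable")
})

test_that("bootstrap SEs are reproducible for a given seed", {
  r <- make_ratios(seq(0.1, 0.9, length.out = 7), 0.2)
  a <- mr_weighted_median(r, n_boot = 300, seed = 99)
  b <- mr_weighted_median(r, n_boot = 300, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(r, n_boot = 300, seed = 100)
  expect_false(identical(a$se, c$se))
})

test_that("mode estimators find the dominant cluster and stay in range", {
  same <- make_ratios(rep(0.7, 5), 0.1)
  expect_warning(est <- mr_mode(same, weighted = FALSE), "identical")
  expect_equal(est$beta, 0.7)
  expect_equal(est$se, 0)

  cluster <- c(0.46, 0.48, 0.49, 0.50, 0.50, 0.51, 0.52, 0.54)
  r <- make_ratios(c(cluster, 2.0, 2.0), 0.1)
  h <- 0.9 * min(sd(r$theta), IQR(r$theta) / 1.349) * 10^(-0.2)
  est_s <- mr_mode(r, weighted = FALSE, n_boot = 100, seed = 2)
  expect_lt(abs(est_s$beta - 0.5), h)

  for (phi in c(1, 2, 4)) {
    m <- mr_mode(r, weighted = TRUE, phi = phi, n_boot = 10, seed = 2)
    expect_gte(m$beta, min(r$theta))
    expect_lte(m$beta, max(r$theta))
  }
})

test_that("wald_summary matches normal theory and the printed-table convention", {
  # printed row: p = 0.0018, OR 1.63 (1.20-2.22) -> back-solve the SE
  beta <- log(1.63)
  se <- beta / qnorm(1 - 0.0018 / 2)
  ws <- wald_summary(beta, se)
  expect_equal(ws$pval, 0.0018, tolerance = 1e-10)
  expect_lt(abs(exp(ws$ci_low) - 1.20), 0.03)
  expect_lt(abs(exp(ws$ci_high) - 2.22), 0.03)

  ws0 <- wald_summary(0, 0.1)
  expect_equal(ws0$pval, 1)
  expect_equal(ws0$ci_low, -ws0$ci_high)

  expect_equal(wald_summary(0.3, 0.1)$pval, wald_summary(-0.3, 0.1)$pval)
})

test_that("all five estimators are equivariant under re-polarization and rescaling", {
  set.seed(17)
  J <- 12
  inst <- make_instruments(beta_exp = abs(rnorm(J, 0.15, 0.05)),
                           beta_out = rnorm(J, 0.07, 0.05),
                           se_out = abs(rnorm(J, 0.05, 0.01)) + 0.01)
  base <- mr_all(inst, n_boot = 150, seed = 4)

  # simultaneous sign flip of both betas: estimates unchanged
  neg <- inst
  neg$beta_exp <- -neg$beta_exp
  neg$beta_out <- -neg$beta_out
  flipped <- mr_all(neg, n_boot = 150, seed = 4)
  expect_equal(flipped$beta, base$beta, tolerance = 1e-9)

  # exposure rescaling by c: estimates scale by 1/c
  c0 <- 2.5
  sc <- inst
  sc$beta_exp <- sc$beta_exp * c0
  sc$se_exp <- sc$se_exp * c0
  scaled <- mr_all(sc, n_boot = 150, seed = 4)
  expect_equal(scaled$beta, base$beta / c0, tolerance = 1e-9)
})

test_that("weighted median resists directional pleiotropy better than IVW", {
  # 40% of instruments share a strong direct effect; truth is beta = 0.5
  set.seed(31)
  J <- 50
  gamma <- abs(rnorm(J, 0.15, 0.06))
  alpha <- c(rnorm(20, 0.8, 0.08), rep(0, 30))
  se_out <- 0.046
  inst <- make_instruments(
    beta_exp = gamma + rnorm(J, 0, 0.012),
    beta_out = 0.5 * gamma + alpha + rnorm(J, 0, se_out),
    se_exp = 0.012, se_out = se_out)
  r <- wald_ratios(inst)
  bias_ivw <- abs(mr_ivw(r)$beta - 0.5)
  bias_wm <- abs(mr_weighted_median(r, n_boot = 100, seed = 7)$beta - 0.5)
  expect_lt(bias_wm, bias_ivw)
})

test_that("mr_all returns one formatted row per requested method", {
  inst <- make_instruments(beta_exp = c(0.1, 0.15, 0.2, 0.25),
                           beta_out = c(0.05, 0.08, 0.1, 0.12))
  out <- mr_all(inst, n_boot = 100, seed = 1)
  expect_equal(out$method, c("ivw", "egger_slope", "weighted_median",
                             "simple_mode", "weighted_mode"))
  expect_true(all(out$nsnp == 4))
  expect_true(all(out$ci_low < out$beta & out$beta < out$ci_high))
  expect_true(all(out$or > 0))
  expect_match(out$or_ci_text, "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}-\\d+\\.\\d{2}\\)$",
               all = TRUE)
  expect_identical(format_or_ci(1.68, 1.24, 2.27), "1.68 (1.24-2.27)")
})
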