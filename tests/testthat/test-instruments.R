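test_that("p-value filtering keeps exactly the sub-threshold records", {
  ss <- make_sumstats(2, pval = c(2e-6, 5e-5))
  kept <- filter_by_pvalue(ss, 1e-5)
  expect_equal(kept$records$variant_id, "rs1")

  expect_equal(nrow(filter_by_pvalue(ss, 1)$records), 2)

  set.seed(42)
  p <- runif(1000)
  big <- make_sumstats(1000, pval = p, pos = 1:1000,
                       eaf = runif(1000, 0.05, 0.95))
  for (thr in c(1e-5, 0.01, 0.5)) {
    expect_equal(nrow(filter_by_pvalue(big, thr)$records), sum(p < thr))
  }
})

test_that("raising the p threshold never decreases the candidate count", {
  set.seed(8)
  ss <- make_sumstats(300, pval = exp(-runif(300, 0, 25)), pos = 1:300,
                      eaf = runif(300, 0.05, 0.95))
  thresholds <- sort(10^seq(-9, 0, length.out = 12))
  counts <- vapply(thresholds,
                   function(t) nrow(filter_by_pvalue(ss, t)$records),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("clumping handles the no-LD and total-LD extremes", {
  n <- 8
  ss <- make_sumstats(n, pos = (1:n) * 1000,
                      pval = seq(1e-8, 1e-6, length.out = n), eaf = 0.3)
  free <- ld_matrix(diag(n), variant_ids = ss$records$variant_id,
                    positions = ss$records$pos)
  expect_setequal(clump(ss, free)$records$variant_id, ss$records$variant_id)

  total <- ld_matrix(matrix(1, n, n), variant_ids = ss$records$variant_id,
                     positions = ss$records$pos)
  kept <- clump(ss, total)
  expect_equal(kept$records$variant_id, "rs1")  # the smallest p

  expect_error(clump(make_sumstats(2, variant_id = c("rs1", "zz9")), free),
               "zz9")
})

test_that("greedy clumping matches an exhaustive reference on random instances", {
  set.seed(2024)
  for (rep in 1:25) {
    inst <- random_clump_instance(20)
    ss <- sumstats(inst$records)
    mine <- clump(ss, inst$ld, r2_threshold = 0.001, window_kb = 10000)
    ref <- clump_reference(inst$records, inst$ld, 0.001, 10000)
    expect_setequal(mine$records$variant_id, ref)

    # order invariance: shuffle input rows
    shuf <- ss
    shuf$records <- ss$records[sample(nrow(ss$records)), ]
    expect_setequal(clump(shuf, inst$ld)$records$variant_id, ref)
  }
})

test_that("lowering the clump r2 threshold never increases the retained count", {
  set.seed(77)
  inst <- random_clump_instance(20)
  ss <- sumstats(inst$records)
  counts <- vapply(c(1, 0.5, 0.1, 0.01, 0.001, 0),
                   function(r2) nrow(clump(ss, inst$ld, r2)$records),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("snp_r2 follows the i-dependent formulas", {
  expect_equal(snp_r2(0.5, 0.1, variant_count = 1), 2 * 0.25 * 0.01)
  expect_equal(snp_r2(0.3, 0, variant_count = 1), 0)
  expect_equal(snp_r2(0.3, 0, se = 0.01, n = 1e4, variant_count = 12), 0)

  num <- 2 * 0.3 * 0.7 * 0.05^2
  den <- num + 2 * 0.3 * 0.7 * 10000 * 0.01^2
  expect_equal(snp_r2(0.3, 0.05, 0.01, 10000, variant_count = 12), num / den)
  expect_lt(snp_r2(0.3, 5, 0.01, 10000, variant_count = 12), 1)

  expect_error(snp_r2(0, 0.1), "degenerate")
  expect_error(snp_r2(1, 0.1), "degenerate")
})

test_that("the F statistic matches hand plug-ins and guards its domain", {
  expect_equal(f_statistic(0.01, 10000, 1), 0.01 * 9998 / 0.99,
               tolerance = 1e-12)
  expect_equal(f_statistic(0, 100, 1), 0)
  expect_equal(f_statistic(0.5, 103, 1), 101)
  expect_error(f_statistic(1, 100, 1), "domain")
  expect_error(f_statistic(0.1, 2, 1), "domain")
})

test_that("weak-instrument filtering drops exactly the SNPs at or below threshold", {
  # per-SNP F spans the threshold: F = r2 (n - 2) / (1 - r2), r2 = 2 eaf (1-eaf) beta^2
  beta <- c(0.02, 0.05, 0.1, 0.2)
  inst <- make_instruments(beta_exp = beta, beta_out = beta * 0.5,
                           eaf = 0.4, n_exp = 5000)
  r2 <- 2 * 0.4 * 0.6 * beta^2
  f <- r2 * (5000 - 2) / (1 - r2)
  iset <- filter_weak_instruments(inst, f_threshold = 10)
  expect_setequal(iset$instruments$variant_id, inst$variant_id[f > 10])
  expect_equal(iset$per_snp_strength$f_snp, f, tolerance = 1e-12)
  expect_equal(range(iset$per_snp_strength$f_snp), range(f))
  expect_match(iset$dropped$reason, "weak_instrument", all = TRUE)

  all_strong <- filter_weak_instruments(
    make_instruments(beta_exp = rep(0.2, 5), beta_out = rep(0.1, 5)))
  expect_equal(nrow(all_strong$instruments), 5)
})

test_that("set-level R2 of independent SNPs is additive and drives set F", {
  inst <- make_instruments(beta_exp = c(0.1, 0.15, 0.2),
                           beta_out = c(0.05, 0.07, 0.1), eaf = 0.25)
  iset <- filter_weak_instruments(inst)
  per <- snp_r2(0.25, c(0.1, 0.15, 0.2))
  expect_equal(iset$set_strength$r2_total, sum(per))
  expect_equal(iset$set_strength$i, 3L)
  expect_equal(iset$set_strength$f_total, f_statistic(sum(per), 18000, 3))

  # >= 10 instruments switch the set-level form to the SE-adjusted one
  beta <- seq(0.1, 0.2, length.out = 12)
  inst12 <- make_instruments(beta_exp = beta, beta_out = beta / 2, eaf = 0.25)
  iset12 <- filter_weak_instruments(inst12)
  expect_equal(iset12$set_strength$r2_total,
               sum(snp_r2(0.25, beta, 0.02, 18000, variant_count = 12)))
})

test_that("confounder exclusion removes listed SNPs and warns on absent ids", {
  ss <- make_sumstats(5, pos = (1:5) * 1000, eaf = 0.3)
  expect_identical(exclude_confounder_snps(ss, character()), ss)
  expect_warning(out <- exclude_confounder_snps(ss, c("rs2", "nope")), "nope")
  expect_equal(nrow(out$records), 4)
  out2 <- exclude_confounder_snps(ss, c("rs1", "rs5"))
  expect_equal(nrow(out2$records), 3)
})

test_that("select_instruments applies the stages in order and logs them", {
  cfg <- sim_config(j_snps = 26, beta_causal = 0.3, seed = 21,
                    ld_blocks = replicate(13, list(size = 2, r2 = 0.9),
                                          simplify = FALSE))
  sim <- simulate_pair(cfg)
  iset <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  expect_identical(iset$filter_log$stage,
                   c("pvalue_filter", "ld_clump", "harmonize",
                     "confounder_exclusion", "f_filter"))
  expect_true(all(iset$filter_log$n_after <= iset$filter_log$n_before))
  strong <- iset$per_snp_strength$variant_id %in% iset$instruments$variant_id
  expect_true(all(iset$per_snp_strength$f_snp[strong] > 10))
  expect_lte(iset$set_strength$i, 13)
  expect_equal(iset$set_strength$i, nrow(iset$instruments))
})
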