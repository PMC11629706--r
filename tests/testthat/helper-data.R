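# Shared fixture builders and independent reference implementations.

# Quick canonical records data frame; override any column by name.
# The row count is `rows` so that the sample-size column `n` can be
# overridden through `...` like any other column.
make_records <- function(rows = 3, ...) {
  out <- data.frame(
    variant_id = sprintf("rs%d", seq_len(rows)),
    chrom = rep_len("1", rows),
    pos = seq_len(rows) * 1000,
    effect_allele = rep_len(c("A", "C", "G"), rows),
    other_allele = rep_len(c("G", "T", "A"), rows),
    eaf = rep_len(c(0.2, 0.3, 0.4), rows),
    beta = rep_len(c(0.1, -0.05, 0.2), rows),
    se = rep_len(0.02, rows),
    pval = rep_len(c(1e-6, 1e-7, 1e-8), rows),
    n = rep_len(10000, rows),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_sumstats <- function(rows = 3, trait_type = "continuous", ...) {
  if (trait_type == "binary") {
    sumstats(make_records(rows, ...), trait_type = "binary",
             n_cases = 1000, n_controls = 9000, allow_missing_eaf = TRUE)
  } else {
    sumstats(make_records(rows, ...), trait_type = trait_type)
  }
}

# Harmonized-instrument data frame built directly (bypasses harmonize()),
# for estimator and sensitivity tests that start from aligned pairs.
make_instruments <- function(beta_exp, beta_out, se_exp = 0.02,
                             se_out = 0.05, eaf = 0.3, n_exp = 18000,
                             n_out = 148000) {
  J <- length(beta_exp)
  data.frame(
    variant_id = paste0("rs", seq_len(J)),
    chrom = "1", pos = seq_len(J) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, J),
    eaf_exp = rep_len(eaf, J), pval_exp = 1e-8,
    n_exp = rep_len(n_exp, J),
    beta_out = beta_out, se_out = rep_len(se_out, J),
    eaf_out = rep_len(eaf, J), n_out = rep_len(n_out, J),
    action_taken = "none", palindromic = FALSE,
    stringsAsFactors = FALSE
  )
}

# Build a wald_ratios data frame directly from theta and se values.
make_ratios <- function(theta, se_theta) {
  out <- data.frame(
    variant_id = paste0("rs", seq_along(theta)),
    theta = theta, se_theta = rep_len(se_theta, length(theta)),
    stringsAsFactors = FALSE
  )
  out$weight <- out$se_theta^-2
  class(out) <- c("wald_ratios", "data.frame")
  out
}

# Independent greedy-clumping reference: each round re-scans the full
# remaining list for the smallest p (ties by chrom, pos, id) and removes
# neighbours in LD. Kept deliberately naive.
clump_reference <- function(records, ld, r2_threshold, window_kb) {
  remaining <- records
  kept <- character(0)
  while (nrow(remaining) > 0) {
    ord <- order(remaining$pval, remaining$chrom, remaining$pos,
                 remaining$variant_id)
    idx <- remaining[ord[1], ]
    kept <- c(kept, idx$variant_id)
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      r <- remaining[i, ]
      if (r$variant_id == idx$variant_id) { drop[i] <- TRUE; next }
      if (r$chrom == idx$chrom &&
          abs(r$pos - idx$pos) <= window_kb * 1000 &&
          ld$r2[idx$variant_id, r$variant_id] >= r2_threshold) {
        drop[i] <- TRUE
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Random LD structure + candidates for clumping oracle checks.
random_clump_instance <- function(n = 20) {
  # random blocks on two chromosomes with random within-block r2
  sizes <- c()
  while (sum(sizes) < n) sizes <- c(sizes, sample(1:4, 1))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]
  block <- rep(seq_along(sizes), sizes)
  m <- matrix(0, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(block == b)
    m[idx, idx] <- runif(1, 0, 1)
  }
  diag(m) <- 1
  chrom <- as.character(1 + (block %% 2))
  # some blocks close together, some far apart
  pos <- cumsum(sample(c(1e3, 1e5, 5e6, 2e7), n, replace = TRUE))
  ids <- paste0("rs", seq_len(n))
  ld <- ld_matrix(m, variant_ids = ids, positions = pos, chrom = chrom)
  rec <- make_records(n, chrom = chrom, pos = pos,
                      pval = signif(runif(n, 1e-12, 1e-4), 3),
                      eaf = runif(n, 0.05, 0.95),
                      beta = rnorm(n, 0, 0.1))
  list(records = rec, ld = ld)
}

# Simulate -> harmonize -> Wald ratios, the common path of the statistical
# validation simulations.
sim_ratios <- function(cfg) {
  sim <- simulate_pair(cfg)
  wald_ratios(harmonize(sim$exposure, sim$outcome))
}
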