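# Synthetic two-sample GWAS generator with known ground truth: emulates a
# continuous exposure GWAS (microbial taxon/pathway abundance) and a binary
# outcome GWAS on the log-odds scale, with block LD, palindromic and
# strand-flipped alleles, and configurable pleiotropy regimes.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a microbiome-exposure /
#' septic-arthritis-outcome MR analysis: exposure GWAS of ~18,340
#' participants, binary outcome GWAS of 1,086 cases among 148,307 subjects,
#' and instruments of post-selection strength (per-allele effects around
#' 0.15 SD, giving per-SNP F well above the weak-instrument cutoff and
#' instrument-strength heterogeneity dominating exposure-side noise).
#'
#' @param j_snps Number of instruments to generate.
#' @param n_exp Exposure GWAS sample size.
#' @param n_out Outcome GWAS sample size (cases + controls).
#' @param case_fraction Outcome case fraction; inflates the outcome SE by
#'   `1/sqrt(case_fraction (1 - case_fraction))` (log-odds scale,
#'   effective-n approximation; no individual-level logistic sampling).
#' @param beta_causal True causal effect, log-odds of outcome per SD of
#'   exposure.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param gamma_dist SNP-exposure effect distribution,
#'   `list(mean =, sd =)` (normal, per-allele, standardized trait).
#' @param pleiotropy `list(type = "none"|"balanced"|"directional",
#'   mean_alpha =, sd_alpha =, frac =)`: direct SNP-outcome effects. `frac`
#'   is the fraction of SNPs that are pleiotropic (invalid): exactly the
#'   first `round(frac * j_snps)` SNPs carry a direct effect, so the invalid
#'   share is fixed by design rather than binomially distributed. Balanced
#'   pleiotropy has zero-mean alpha, directional a shifted mean.
#' @param inside_violated Correlate the direct effects with instrument
#'   strength (violating InSIDE; correlation 0.6).
#' @param ld_blocks `NULL` for mutually independent SNPs, or a list of
#'   `list(size =, r2 =)` blocks partitioning `j_snps`.
#' @param palindrome_fraction Fraction of SNPs given A/T or C/G alleles.
#' @param strand_flip_fraction Fraction of outcome records written on the
#'   opposite strand.
#' @param seed Integer seed. One global seed drives a per-SNP substream, so
#'   increasing `j_snps` never perturbs earlier SNPs' draws.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(j_snps = 50,
                       n_exp = 18340,
                       n_out = 148307,
                       case_fraction = 1086 / 148307,
                       beta_causal = 0,
                       maf_range = c(0.2, 0.5),
                       gamma_dist = list(mean = 0.15, sd = 0.06),
                       pleiotropy = list(type = "none", mean_alpha = 0,
                                         sd_alpha = 0.08, frac = 1),
                       inside_violated = FALSE,
                       ld_blocks = NULL,
                       palindrome_fraction = 0.2,
                       strand_flip_fraction = 0.1,
                       seed = 1L) {
  pleiotropy <- utils::modifyList(
    list(type = "none", mean_alpha = 0, sd_alpha = 0.08, frac = 1),
    pleiotropy)
  stopifnot(
    j_snps >= 1, n_exp >= 2, n_out >= 2,
    case_fraction > 0, case_fraction < 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    gamma_dist$sd >= 0, pleiotropy$sd_alpha >= 0,
    pleiotropy$frac >= 0, pleiotropy$frac <= 1,
    pleiotropy$type %in% c("none", "balanced", "directional"),
    palindrome_fraction >= 0, palindrome_fraction <= 1,
    strand_flip_fraction >= 0, strand_flip_fraction <= 1
  )
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, function(b) b$size, numeric(1))
    if (sum(sizes) != j_snps) {
      stop("config error: ld_blocks sizes must sum to j_snps", call. = FALSE)
    }
  }
  structure(
    list(j_snps = as.integer(j_snps), n_exp = n_exp, n_out = n_out,
         case_fraction = case_fraction, beta_causal = beta_causal,
         maf_range = maf_range, gamma_dist = gamma_dist,
         pleiotropy = pleiotropy, inside_violated = inside_violated,
         ld_blocks = ld_blocks, palindrome_fraction = palindrome_fraction,
         strand_flip_fraction = strand_flip_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic per-SNP substream seed from the global seed.
#
# R seeds the Mersenne-Twister state from the user seed with a weak linear
# scramble, so streams started from nearby seeds are noticeably correlated;
# replicate seeds must therefore be separated by a strong integer hash
# before reaching set.seed(). This is splitmix32, done in exact 32-bit
# arithmetic on doubles (all intermediates stay below 2^53).

.mul32 <- function(a, b) {
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536 * 65536
  (lo + hi) %% 4294967296
}

.xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

.hash32 <- function(x) {
  x <- (x + 2654435769) %% 4294967296
  x <- .xor32(x, x %/% 65536)
  x <- .mul32(x, 569420461)
  x <- .xor32(x, x %/% 32768)
  x <- .mul32(x, 1935289751)
  x <- .xor32(x, x %/% 32768)
  x
}

.snp_seed <- function(seed, j) {
  h <- .hash32(.hash32(as.numeric(seed) %% 4294967296) + j)
  as.integer(h %% 2147483647)
}

# Block id per SNP (singletons when ld_blocks is NULL).
.block_index <- function(cfg) {
  if (is.null(cfg$ld_blocks)) return(seq_len(cfg$j_snps))
  rep(seq_along(cfg$ld_blocks),
      vapply(cfg$ld_blocks, function(b) b$size, numeric(1)))
}

# Positions: blocks separated by twice the default 10,000 kb clumping
# window, SNPs within a block 1 kb apart. Single chromosome.
.sim_positions <- function(cfg) {
  block <- .block_index(cfg)
  within <- stats::ave(seq_along(block), block, FUN = seq_along)
  1e6 + (block - 1) * 2e7 + (within - 1) * 1000
}

.PALIN_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.NONPALIN_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                        c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' For each SNP: draws a MAF and a SNP-exposure effect `gamma_j`; draws a
#' direct (pleiotropic) SNP-outcome effect `alpha_j` per the configured
#' regime; sets the true outcome effect `Gamma_j = beta_causal * gamma_j +
#' alpha_j`; and observes both effects with normal noise at the analytic
#' standard errors `se_exp = 1/sqrt(2 maf (1-maf) n_exp)` and
#' `se_out = 1/sqrt(2 maf (1-maf) n_out cf (1-cf))`. Alleles are assigned
#' with the configured palindromic fraction, and the configured fraction of
#' outcome records is written on the opposite strand.
#'
#' @param cfg A [sim_config()].
#' @return List `(exposure, outcome, truth, ld)`: two [sumstats] objects, a
#'   truth data frame carrying every latent quantity
#'   (`maf, gamma, alpha, big_gamma, pleiotropic, palindromic,
#'   strand_flipped`), and the matching [ld_matrix] from
#'   [simulate_ld_blocks()].
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- cfg$j_snps
  pos <- .sim_positions(cfg)
  cf <- cfg$case_fraction
  pl <- cfg$pleiotropy

  rows_exp <- vector("list", J)
  rows_out <- vector("list", J)
  truth <- vector("list", J)

  for (j in seq_len(J)) {
    res <- .with_seed(.snp_seed(cfg$seed, j), {
      maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      z_g <- stats::rnorm(1)
      gamma <- cfg$gamma_dist$mean + cfg$gamma_dist$sd * z_g
      z_a <- stats::rnorm(1)
      is_pleio <- pl$type != "none" && j <= round(pl$frac * J)
      alpha <- 0
      if (is_pleio) {
        mu <- if (pl$type == "directional") pl$mean_alpha else 0
        noise <- if (cfg$inside_violated) {
          0.6 * z_g + sqrt(1 - 0.36) * z_a
        } else z_a
        alpha <- mu + pl$sd_alpha * noise
      }
      big_gamma <- cfg$beta_causal * gamma + alpha
      v <- 2 * maf * (1 - maf)
      se_exp <- 1 / sqrt(v * cfg$n_exp)
      se_out <- 1 / sqrt(v * cfg$n_out * cf * (1 - cf))
      beta_exp <- gamma + stats::rnorm(1) * se_exp
      beta_out <- big_gamma + stats::rnorm(1) * se_out
      palin <- stats::runif(1) < cfg$palindrome_fraction
      flip <- stats::runif(1) < cfg$strand_flip_fraction
      pair <- if (palin) {
        .PALIN_PAIRS[[sample.int(4, 1)]]
      } else {
        .NONPALIN_PAIRS[[sample.int(8, 1)]]
      }
      eaf_out <- min(max(maf + stats::rnorm(1, 0, 0.005), 0.01), 0.99)
      list(maf = maf, gamma = gamma, alpha = alpha, big_gamma = big_gamma,
           is_pleio = is_pleio, se_exp = se_exp, se_out = se_out,
           beta_exp = beta_exp, beta_out = beta_out, palin = palin,
           flip = flip, ea = pair[1], oa = pair[2], eaf_out = eaf_out)
    })
    id <- paste0("rs", j)
    rows_exp[[j]] <- data.frame(
      variant_id = id, chrom = "1", pos = pos[j],
      effect_allele = res$ea, other_allele = res$oa,
      eaf = res$maf, beta = res$beta_exp, se = res$se_exp,
      pval = max(2 * stats::pnorm(-abs(res$beta_exp / res$se_exp)), 1e-300),
      n = cfg$n_exp, stringsAsFactors = FALSE)
    ea_o <- if (res$flip) complement_allele(res$ea) else res$ea
    oa_o <- if (res$flip) complement_allele(res$oa) else res$oa
    rows_out[[j]] <- data.frame(
      variant_id = id, chrom = "1", pos = pos[j],
      effect_allele = ea_o, other_allele = oa_o,
      eaf = res$eaf_out, beta = res$beta_out, se = res$se_out,
      pval = max(2 * stats::pnorm(-abs(res$beta_out / res$se_out)), 1e-300),
      n = cfg$n_out, stringsAsFactors = FALSE)
    truth[[j]] <- data.frame(
      variant_id = id, maf = res$maf, gamma = res$gamma, alpha = res$alpha,
      big_gamma = res$big_gamma, pleiotropic = res$is_pleio,
      palindromic = res$palin, strand_flipped = res$flip,
      stringsAsFactors = FALSE)
  }

  exposure <- sumstats(do.call(rbind, rows_exp),
                       trait_id = "sim_exposure", trait_type = "continuous")
  n_cases <- round(cfg$n_out * cf)
  outcome <- sumstats(do.call(rbind, rows_out),
                      trait_id = "sim_outcome", trait_type = "binary",
                      n_cases = n_cases, n_controls = cfg$n_out - n_cases)
  truth <- do.call(rbind, truth)
  attr(truth, "beta_causal") <- cfg$beta_causal
  list(exposure = exposure, outcome = outcome, truth = truth,
       ld = simulate_ld_blocks(cfg))
}

#' Block-diagonal LD matrix for a simulation configuration
#'
#' Within-block entries take the block's configured r-squared, across-block
#' entries are zero, and the diagonal is one. Positions place all SNPs of a
#' block inside one clumping window and separate blocks by more than the
#' default window, so clumping retains exactly one SNP per block when the
#' block r-squared exceeds the clumping threshold.
#'
#' @param cfg A [sim_config()].
#' @return An [ld_matrix].
#' @export
simulate_ld_blocks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- cfg$j_snps
  block <- .block_index(cfg)
  r2_by_block <- if (is.null(cfg$ld_blocks)) {
    rep(0, J)
  } else {
    vapply(cfg$ld_blocks, function(b) b$r2, numeric(1))
  }
  m <- matrix(0, J, J)
  for (b in unique(block)) {
    idx <- which(block == b)
    m[idx, idx] <- r2_by_block[b]
  }
  diag(m) <- 1
  ld_matrix(m, variant_ids = paste0("rs", seq_len(J)),
            positions = .sim_positions(cfg), chrom = "1")
}

#' Write a named suite of simulation fixtures
#'
#' Generates five fixed scenarios — `null` (no causal effect), a
#' `strong_positive` risk signal (OR about 1.6), a `protective` signal (OR
#' about 0.7), a `directional_pleiotropy` trap (no causal effect, 40% of
#' SNPs carrying a strong shifted direct effect), and a `high_heterogeneity`
#' scenario (balanced pleiotropy on every SNP) — each as summary-statistic,
#' LD and truth tables under `out_dir/<scenario>/`, with a JSON manifest
#' recording every scenario's seed and ground truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; scenario seeds are derived from it.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- as.integer(as.numeric(seed) %% 2^27)
  blocks13 <- replicate(13, list(size = 2, r2 = 0.9), simplify = FALSE)
  scenarios <- list(
    null = sim_config(j_snps = 26, beta_causal = 0, ld_blocks = blocks13,
                      seed = base + 101L),
    strong_positive = sim_config(j_snps = 26, beta_causal = log(1.63),
                                 ld_blocks = blocks13, seed = base + 202L),
    protective = sim_config(j_snps = 26, beta_causal = log(0.7),
                            ld_blocks = blocks13, seed = base + 303L),
    directional_pleiotropy = sim_config(
      j_snps = 26, beta_causal = 0,
      pleiotropy = list(type = "directional", mean_alpha = 0.8,
                        sd_alpha = 0.08, frac = 0.4),
      ld_blocks = blocks13, seed = base + 404L),
    high_heterogeneity = sim_config(
      j_snps = 26, beta_causal = log(1.63),
      pleiotropy = list(type = "balanced", mean_alpha = 0, sd_alpha = 0.5,
                        frac = 1),
      ld_blocks = blocks13, seed = base + 505L)
  )
  manifest <- list(master_seed = as.integer(seed), scenarios = list())
  for (name in names(scenarios)) {
    cfg <- scenarios[[name]]
    sim <- simulate_pair(cfg)
    dir <- file.path(out_dir, name)
    dir.create(dir, showWarnings = FALSE)
    write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
    write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
    write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$scenarios[[name]] <- list(
      seed = cfg$seed, j_snps = cfg$j_snps,
      beta_causal = cfg$beta_causal, true_or = exp(cfg$beta_causal),
      pleiotropy = cfg$pleiotropy$type,
      exposure = file.path(name, "exposure.tsv"),
      outcome = file.path(name, "outcome.tsv"),
      ld = file.path(name, "ld.tsv"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
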