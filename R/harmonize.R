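# Exposure-outcome harmonization: align both studies onto one effect allele
# per SNP, resolving strand flips and palindromic ambiguity.

#' Complement a nucleotide base
#'
#' @param a Character vector of bases in `{A,C,G,T}`.
#' @return The Watson-Crick complement(s): A<->T, C<->G.
#' @export
#' @examples
#' complement_allele("A")  # "T"
complement_allele <- function(a) {
  map <- c(A = "T", T = "A", C = "G", G = "C")
  a <- toupper(a)
  if (any(!a %in% names(map))) {
    stop("allele(s) not in {A,C,G,T}: ",
         paste(unique(a[!a %in% names(map)]), collapse = ", "), call. = FALSE)
  }
  unname(map[a])
}

.is_palindromic <- function(ea, oa) oa == complement_allele(ea)

#' Harmonize exposure and outcome summary statistics
#'
#' For every SNP present in both studies, the outcome association is
#' re-expressed on the exposure's effect allele:
#'
#' * identical alleles: kept unchanged;
#' * swapped alleles: outcome beta negated, outcome EAF complemented;
#' * strand complements: alleles complemented, then the same logic applied;
#' * palindromic SNPs (A/T or C/G): allele labels cannot distinguish a swap
#'   from a strand flip, so orientation is resolved from allele frequency
#'   alone — kept only when both EAFs lie outside
#'   `[0.5 - margin, 0.5 + margin]`; EAFs on the same side of 0.5 imply the
#'   same effect allele, opposite sides imply a swap. Otherwise dropped with
#'   reason `"palindromic_ambiguous"` (always dropped when outcome EAF is
#'   missing);
#' * irreconcilable allele pairs: dropped with reason `"allele_mismatch"`.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_margin Half-width of the ambiguous EAF band around
#'   0.5 (default 0.08: palindromes kept only when both EAFs < 0.42 or
#'   > 0.58).
#' @return Object of class `harmonized_set`: list with `instruments` (data
#'   frame of aligned per-SNP pairs, one row per retained SNP, columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, beta_exp, se_exp,
#'   eaf_exp, pval_exp, n_exp, beta_out, se_out, eaf_out, n_out,
#'   action_taken, palindromic`), `dropped` (data frame `variant_id,
#'   reason`), and the two trait ids. The union of `instruments` and
#'   `dropped` partitions the shared variants.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_margin = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  stopifnot(palindrome_eaf_margin >= 0, palindrome_eaf_margin <= 0.5)
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0) stop("no shared variants", call. = FALSE)
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  n <- length(shared)
  keep <- logical(n)
  action <- character(n)
  reason <- character(n)
  palin <- .is_palindromic(ex$effect_allele, ex$other_allele)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  for (i in seq_len(n)) {
    ea_e <- ex$effect_allele[i]; oa_e <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]
    if (.is_palindromic(ea_o, oa_o) != palin[i]) {
      reason[i] <- "allele_mismatch"
      next
    }
    if (palin[i]) {
      # Orientation from EAF only; allele labels carry no strand information.
      if (is.na(eaf_out[i]) ||
          abs(ex$eaf[i] - 0.5) <= palindrome_eaf_margin ||
          abs(eaf_out[i] - 0.5) <= palindrome_eaf_margin) {
        reason[i] <- "palindromic_ambiguous"
        next
      }
      if (!setequal(c(ea_o, oa_o), c(ea_e, oa_e)) &&
          !setequal(c(ea_o, oa_o),
                    complement_allele(c(ea_e, oa_e)))) {
        reason[i] <- "allele_mismatch"
        next
      }
      if ((ex$eaf[i] - 0.5) * (eaf_out[i] - 0.5) > 0) {
        keep[i] <- TRUE
        action[i] <- "none"
      } else {
        keep[i] <- TRUE
        action[i] <- "swapped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    if (ea_o == ea_e && oa_o == oa_e) {
      keep[i] <- TRUE; action[i] <- "none"
    } else if (ea_o == oa_e && oa_o == ea_e) {
      keep[i] <- TRUE; action[i] <- "swapped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else {
      cea <- complement_allele(ea_o); coa <- complement_allele(oa_o)
      if (cea == ea_e && coa == oa_e) {
        keep[i] <- TRUE; action[i] <- "strand_flipped"
      } else if (cea == oa_e && coa == ea_e) {
        keep[i] <- TRUE; action[i] <- "swapped_and_flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else {
        reason[i] <- "allele_mismatch"
      }
    }
  }

  inst <- data.frame(
    variant_id = shared[keep],
    chrom = ex$chrom[keep],
    pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    eaf_exp = ex$eaf[keep],
    pval_exp = ex$pval[keep],
    n_exp = ex$n[keep],
    beta_out = beta_out[keep],
    se_out = ou$se[keep],
    eaf_out = eaf_out[keep],
    n_out = ou$n[keep],
    action_taken = action[keep],
    palindromic = palin[keep],
    stringsAsFactors = FALSE
  )
  dropped <- data.frame(
    variant_id = shared[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(instruments = inst, dropped = dropped,
         exposure_id = exposure$trait_id, outcome_id = outcome$trait_id),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instruments, %d dropped\n",
              x$exposure_id, x$outcome_id,
              nrow(x$instruments), nrow(x$dropped)))
  invisible(x)
}
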