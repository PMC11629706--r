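# Canonical data model: GWAS summary statistics and LD matrices.
# Coordinates are 1-based (GWAS convention). Alleles are single bases A/C/G/T;
# indels and multi-allelic records are rejected.

#' Default column-name mapping for summary-statistic tables
#'
#' Maps the canonical internal field names to GWAS-SSF-style column names.
#' Pass a modified copy to [read_sumstats()] for files with other headers.
#'
#' @return Named character vector: internal field -> file column name.
#' @export
default_schema <- function() {
  c(
    variant_id    = "variant_id",
    chrom         = "chromosome",
    pos           = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    eaf           = "effect_allele_frequency",
    beta          = "beta",
    se            = "standard_error",
    pval          = "p_value",
    n             = "n"
  )
}

.canonical_fields <- function() names(default_schema())

#' Construct a GWAS summary-statistics object
#'
#' @param records Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_id Label for the trait (e.g. an accession-like string).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_cases,n_controls Case/control counts; required iff `trait_type`
#'   is `"binary"`. When per-record `n` is absent it is imputed as
#'   `n_cases + n_controls`.
#' @param allow_missing_eaf Permit `NA` effect-allele frequencies (outcome
#'   side only; exposure-side records without EAF cannot enter instrument
#'   strength computation).
#' @param validate Run row-level invariant checks (default `TRUE`).
#'
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type`, `n_cases`, `n_controls` and `records`.
#' @export
sumstats <- function(records, trait_id = "trait", trait_type = "continuous",
                     n_cases = NA_integer_, n_controls = NA_integer_,
                     allow_missing_eaf = FALSE, validate = TRUE) {
  stopifnot(is.data.frame(records))
  trait_type <- match.arg(trait_type, c("continuous", "binary"))
  if (trait_type == "binary" && (is.na(n_cases) || is.na(n_controls))) {
    stop("binary traits require n_cases and n_controls", call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.canonical_fields(), names(records))
  if ("n" %in% missing_cols && trait_type == "binary") {
    records$n <- n_cases + n_controls
    missing_cols <- setdiff(missing_cols, "n")
  }
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, .canonical_fields(), drop = FALSE]
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  records$chrom <- as.character(records$chrom)
  records$variant_id <- as.character(records$variant_id)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  if (validate) {
    dup <- unique(records$variant_id[duplicated(records$variant_id)])
    if (length(dup) > 0) {
      stop("duplicate variant_id: ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    bad <- validate_records(records, allow_missing_eaf = allow_missing_eaf)
    if (nrow(bad) > 0) {
      stop("invalid records:\n",
           paste(sprintf("  %s: %s", bad$variant_id, bad$reason),
                 collapse = "\n"),
           call. = FALSE)
    }
  }

  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         n_cases = n_cases, n_controls = n_controls, records = records),
    class = "sumstats"
  )
}

#' Row-level invariant check for variant association records
#'
#' Validation is total: every row is either fully valid or reported with a
#' reason; no partially-invalid record survives into a `sumstats` object.
#'
#' @param records Data frame in canonical column layout.
#' @param allow_missing_eaf Permit `NA` EAF values.
#' @return Data frame `(variant_id, reason)` of rejected rows (possibly empty).
#' @export
validate_records <- function(records, allow_missing_eaf = FALSE) {
  bases <- c("A", "C", "G", "T")
  reasons <- character(nrow(records))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- msg
  }
  flag(!(records$effect_allele %in% bases), "effect allele not a single base A/C/G/T")
  flag(!(records$other_allele %in% bases), "other allele not a single base A/C/G/T")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  if (allow_missing_eaf) {
    eaf_bad <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  } else {
    eaf_bad <- is.na(records$eaf) | records$eaf < 0 | records$eaf > 1
  }
  reasons[eaf_bad & reasons == ""] <- "eaf outside [0,1]"
  flag(!(records$se > 0), "nonpositive SE")
  flag(!(records$pval > 0 & records$pval <= 1), "p-value outside (0,1]")
  flag(!(records$n >= 2), "sample size below 2")
  flag(!(records$pos >= 1), "position not a positive 1-based coordinate")
  data.frame(
    variant_id = records$variant_id[reasons != ""],
    reason = reasons[reasons != ""],
    stringsAsFactors = FALSE
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  if (x$trait_type == "binary") {
    cat(sprintf("  cases: %s  controls: %s\n", x$n_cases, x$n_controls))
  }
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited (tab by default) per-variant association table, renames
#' columns via `schema`, upper-cases alleles and validates every row. Rows
#' violating record invariants are rejected; by default this is an error
#' listing each offending row and reason, with `reject_action = "drop"` they
#' are dropped and the rejection report attached as attribute `"rejected"`.
#'
#' @param path File path of a delimited table.
#' @param schema Named character vector mapping internal field names to the
#'   file's column names; see [default_schema()].
#' @param sep Field separator (default tab).
#' @param reject_action `"error"` (default) or `"drop"`.
#' @inheritParams sumstats
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, schema = default_schema(), sep = "\t",
                          trait_id = basename(path),
                          trait_type = "continuous",
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          allow_missing_eaf = FALSE,
                          reject_action = c("error", "drop")) {
  reject_action <- match.arg(reject_action)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  schema <- schema[names(schema) %in% .canonical_fields()]
  required <- schema[setdiff(names(schema), if (trait_type == "binary") "n" else character())]
  absent <- required[!(required %in% names(tab))]
  if (length(absent) > 0) {
    stop("schema error: mapped column(s) not found in file: ",
         paste(sprintf("%s (-> %s)", absent, names(absent)), collapse = ", "),
         call. = FALSE)
  }
  present <- schema[schema %in% names(tab)]
  out <- tab[, present, drop = FALSE]
  names(out) <- names(present)

  if (reject_action == "drop" && nrow(out) > 0) {
    out$effect_allele <- toupper(as.character(out$effect_allele))
    out$other_allele <- toupper(as.character(out$other_allele))
    bad <- validate_records(out, allow_missing_eaf = allow_missing_eaf)
    keep <- !(out$variant_id %in% bad$variant_id)
    ss <- sumstats(out[keep, , drop = FALSE], trait_id = trait_id,
                   trait_type = trait_type, n_cases = n_cases,
                   n_controls = n_controls,
                   allow_missing_eaf = allow_missing_eaf)
    attr(ss, "rejected") <- bad
    return(ss)
  }
  sumstats(out, trait_id = trait_id, trait_type = trait_type,
           n_cases = n_cases, n_controls = n_controls,
           allow_missing_eaf = allow_missing_eaf)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a GWAS summary-statistics table
#'
#' Deterministic column order (the canonical field order) and full float
#' precision: numeric fields are printed with 17 significant digits so a
#' write/read round trip is lossless for doubles.
#'
#' @param s A [sumstats] object.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path, sep = "\t") {
  stopifnot(inherits(s, "sumstats"))
  rec <- s$records
  out <- data.frame(
    variant_id = rec$variant_id,
    chromosome = rec$chrom,
    base_pair_location = .fmt_num(rec$pos),
    effect_allele = rec$effect_allele,
    other_allele = rec$other_allele,
    effect_allele_frequency = .fmt_num(rec$eaf),
    beta = .fmt_num(rec$beta),
    standard_error = .fmt_num(rec$se),
    p_value = .fmt_num(rec$pval),
    n = .fmt_num(rec$n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = sep), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = sep)), con)
  }
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' @param r2 Square numeric matrix of squared correlations in `[0,1]`.
#' @param variant_ids Variant identifiers, one per row/column.
#' @param positions 1-based coordinates aligned to `variant_ids`.
#' @param chrom Chromosome labels aligned to `variant_ids` (recycled).
#' @return Object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2),
                      positions = seq_len(nrow(r2)), chrom = "1") {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("shape error: LD matrix must be square", call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(nrow(r2)))
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE) || anyNA(r2)) {
    stop("range error: LD entries must lie in [0,1]", call. = FALSE)
  }
  asym <- max(abs(r2 - t(r2)))
  if (asym > 1e-8) stop("LD matrix asymmetric beyond 1e-8", call. = FALSE)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(
    list(variant_ids = as.character(variant_ids), r2 = r2,
         positions = as.numeric(positions),
         chrom = rep_len(as.character(chrom), nrow(r2))),
    class = "ld_matrix"
  )
}

#' Read a square LD (r-squared) matrix
#'
#' Expects a tab-separated square numeric table with variant identifiers as
#' the header row and first column. Asymmetry beyond 1e-8 is an error; below
#' that the matrix is symmetrized by averaging.
#'
#' @param path File path.
#' @param positions Optional coordinates (defaults to row order); positions
#'   written by [write_ld_matrix()] are recovered from the companion columns
#'   when present.
#' @return An [ld_matrix] object.
#' @export
read_ld_matrix <- function(path, positions = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  has_meta <- all(c("..chrom", "..pos") %in% names(tab))
  chrom <- "1"
  if (has_meta) {
    chrom <- as.character(tab[["..chrom"]])
    positions <- as.numeric(tab[["..pos"]])
    tab <- tab[, setdiff(names(tab), c("..chrom", "..pos")), drop = FALSE]
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("shape error: LD matrix must be square", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- ids
  if (is.null(positions)) positions <- seq_along(ids)
  ld_matrix(m, variant_ids = ids, positions = positions, chrom = chrom)
}

#' Write an LD matrix with its positional metadata
#'
#' @param ld An [ld_matrix] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  n <- length(ld$variant_ids)
  header <- paste(c("variant_id", ld$variant_ids, "..chrom", "..pos"),
                  collapse = "\t")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(ld$variant_ids[i], .fmt_num(ld$r2[i, ]), ld$chrom[i],
            .fmt_num(ld$positions[i])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
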