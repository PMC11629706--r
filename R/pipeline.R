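# Orchestration: select -> harmonize -> fit -> sensitivity across many
# exposures against one outcome; Table-style report and plot-ready files.

#' Assemble and validate a pipeline run configuration
#'
#' @param exposures Named list: each element a [sumstats] object or the path
#'   of a summary-statistics file. Names become `exposure_id`s.
#' @param outcome A [sumstats] object or file path.
#' @param ld An [ld_matrix] object or file path.
#' @param classification Character vector recycled over exposures (taxonomic
#'   level or `"pathway"`); carried verbatim into the report.
#' @param pval_threshold,clump_r2,clump_kb,f_threshold Instrument-selection
#'   thresholds (defaults 1e-5, 0.001, 10000 kb, 10).
#' @param exclusion_list Confounder SNP identifiers (default empty: a
#'   confounder review that clears every instrument).
#' @param methods Estimators to fit (see [mr_all()]).
#' @param effects_model IVW effects model.
#' @param alpha Significance level for the IVW decision rule (default 0.05).
#' @param n_boot,seed Bootstrap settings.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param outcome_n_cases,outcome_n_controls Case/control counts, required
#'   when `outcome` is a file path.
#' @param palindrome_eaf_margin Passed to [harmonize()].
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(exposures, outcome, ld,
                       classification = "unclassified",
                       pval_threshold = 1e-5, clump_r2 = 0.001,
                       clump_kb = 10000, f_threshold = 10,
                       exclusion_list = character(),
                       methods = c("ivw", "egger", "weighted_median",
                                   "simple_mode", "weighted_mode"),
                       effects_model = "multiplicative_random",
                       alpha = 0.05, n_boot = 1000, seed = 20241126,
                       out_dir = NULL,
                       outcome_n_cases = NA_integer_,
                       outcome_n_controls = NA_integer_,
                       palindrome_eaf_margin = 0.08) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(exposures) > 0 &&
      (is.null(names(exposures)) || any(names(exposures) == ""))) {
    stop("exposures must be a fully named list", call. = FALSE)
  }
  for (e in exposures) {
    if (is.character(e) && !file.exists(e)) {
      stop("exposure file not found: ", e, call. = FALSE)
    }
  }
  if (is.character(outcome) && !file.exists(outcome)) {
    stop("outcome file not found: ", outcome, call. = FALSE)
  }
  if (is.character(ld) && !file.exists(ld)) {
    stop("LD file not found: ", ld, call. = FALSE)
  }
  structure(
    list(exposures = exposures, outcome = outcome, ld = ld,
         classification = rep_len(classification, length(exposures)),
         pval_threshold = pval_threshold, clump_r2 = clump_r2,
         clump_kb = clump_kb, f_threshold = f_threshold,
         exclusion_list = exclusion_list, methods = methods,
         effects_model = effects_model, alpha = alpha,
         n_boot = n_boot, seed = seed, out_dir = out_dir,
         outcome_n_cases = outcome_n_cases,
         outcome_n_controls = outcome_n_controls,
         palindrome_eaf_margin = palindrome_eaf_margin),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds the same fields as [run_config()]; `exposures` may be a
#' named mapping of file paths. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path YAML (`.yaml`/`.yml`, requires the yaml package) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  raw$exposures <- lapply(raw$exposures, resolve)
  raw$outcome <- resolve(raw$outcome)
  raw$ld <- resolve(raw$ld)
  do.call(run_config, raw)
}

.load_sumstats <- function(x, ...) {
  if (inherits(x, "sumstats")) return(x)
  read_sumstats(x, ...)
}

#' Run the full MR pipeline over many exposures
#'
#' For every exposure, applies the selection stages in order (p-value filter,
#' LD clumping, harmonization, confounder exclusion, F filtering), fits the
#' requested estimators, runs the sensitivity suite, and emits one report
#' row. Exposures ending with fewer than 2 instruments are reported with
#' status `"insufficient instruments"`; a failure in one exposure never
#' affects another (errors are captured per exposure and the run continues).
#'
#' @param cfg A `run_config` (or path to one; see [read_run_config()]).
#' @return Object of class `mr_pipeline_result`: list with `report` (one row
#'   per exposure), `estimates`, `loo`, `filter_log` (all long data frames
#'   keyed by `exposure_id`), and `config`. When `cfg$out_dir` is set,
#'   [render_report()] is called on the result before returning.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  outcome <- .load_sumstats(cfg$outcome, trait_type = "binary",
                            n_cases = cfg$outcome_n_cases,
                            n_controls = cfg$outcome_n_controls,
                            allow_missing_eaf = TRUE)
  ld <- if (inherits(cfg$ld, "ld_matrix")) cfg$ld else read_ld_matrix(cfg$ld)

  report <- list(); estimates <- list(); loo_tabs <- list(); logs <- list()
  for (k in seq_along(cfg$exposures)) {
    eid <- names(cfg$exposures)[k]
    row <- data.frame(
      classification = cfg$classification[k], exposure_id = eid,
      nsnp = NA_integer_, ivw_p = NA_real_, or_ci_text = NA_character_,
      egger_intercept = NA_real_, intercept_p = NA_real_,
      q = NA_real_, q_p = NA_real_, steiger = NA,
      significant = NA, status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      exposure <- .load_sumstats(cfg$exposures[[k]], trait_id = eid)
      iset <- select_instruments(
        exposure, outcome, ld,
        pval_threshold = cfg$pval_threshold, clump_r2 = cfg$clump_r2,
        clump_kb = cfg$clump_kb, f_threshold = cfg$f_threshold,
        exclusion_list = cfg$exclusion_list,
        palindrome_eaf_margin = cfg$palindrome_eaf_margin)
      logs[[eid]] <- cbind(exposure_id = eid, iset$filter_log)
      if (nrow(iset$instruments) < 2) {
        row$nsnp <- nrow(iset$instruments)
        row$status <- "insufficient instruments"
        row
      } else {
        ests <- mr_all(iset, methods = cfg$methods,
                       effects_model = cfg$effects_model,
                       n_boot = cfg$n_boot, seed = cfg$seed)
        estimates[[eid]] <- cbind(exposure_id = eid, ests)
        sens <- sensitivity_suite(iset, cfg$effects_model,
                                  alpha = cfg$alpha)
        loo_tabs[[eid]] <- cbind(exposure_id = eid, sens$loo)
        ivw <- ests[ests$method == "ivw", ]
        row$nsnp <- ivw$nsnp
        row$ivw_p <- ivw$pval
        row$or_ci_text <- ivw$or_ci_text
        row$egger_intercept <- sens$pleiotropy$estimate
        row$intercept_p <- sens$pleiotropy$pval
        qrow <- sens$heterogeneity[sens$heterogeneity$method == "ivw", ]
        row$q <- qrow$q
        row$q_p <- qrow$pval
        row$steiger <- sens$steiger$correct_direction
        row
      }
    }, error = function(e) {
      row$status <- paste("error:", conditionMessage(e))
      row
    })
    report[[eid]] <- res
  }

  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(classification = character(), exposure_id = character(),
               nsnp = integer(), ivw_p = numeric(),
               or_ci_text = character(), egger_intercept = numeric(),
               intercept_p = numeric(), q = numeric(), q_p = numeric(),
               steiger = logical(), significant = logical(),
               status = character(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  report <- flag_significant(report, cfg$alpha)
  result <- structure(
    list(report = report,
         estimates = if (length(estimates) > 0) do.call(rbind, estimates) else NULL,
         loo = if (length(loo_tabs) > 0) do.call(rbind, loo_tabs) else NULL,
         filter_log = if (length(logs) > 0) do.call(rbind, logs) else NULL,
         config = cfg),
    class = "mr_pipeline_result")
  if (!is.null(result$estimates)) rownames(result$estimates) <- NULL
  if (!is.null(result$loo)) rownames(result$loo) <- NULL
  if (!is.null(result$filter_log)) rownames(result$filter_log) <- NULL
  if (!is.null(cfg$out_dir)) render_report(result, cfg$out_dir)
  result
}

#' Apply the IVW significance rule
#'
#' Marks a row significant when `ivw_p < alpha` (strict inequality). No
#' multiplicity adjustment is applied by default — the raw per-exposure rule;
#' with `adjust = TRUE` a Benjamini-Hochberg FDR column `ivw_p_bh` is added
#' (the raw rule across hundreds of exposures is a known limitation).
#'
#' @param rows Report data frame containing `ivw_p`.
#' @param alpha Significance level (default 0.05).
#' @param adjust Add a BH-adjusted p-value column.
#' @return The data frame with a logical `significant` column (and
#'   optionally `ivw_p_bh`).
#' @export
flag_significant <- function(rows, alpha = 0.05, adjust = FALSE) {
  rows$significant <- !is.na(rows$ivw_p) & rows$ivw_p < alpha
  if (adjust) rows$ivw_p_bh <- stats::p.adjust(rows$ivw_p, method = "BH")
  rows
}

#' Write the pipeline report and plot-ready tables
#'
#' Emits, under `out_dir`:
#' * `report.tsv` — one row per exposure in Table style (classification,
#'   exposure, nsnp, IVW p, "OR (low-high)", Egger intercept and p, Q and p,
#'   Steiger verdict, significance);
#' * `forest.tsv` — method/beta/CI per exposure (forest-plot input);
#' * `leave_one_out.tsv` — the leave-one-out IVW table per exposure;
#' * `pvalue_matrix.tsv` — exposures x methods p-value matrix with a
#'   companion `*_sig` flag column per method;
#' * `run_summary.json` — machine-readable run metadata and the report.
#'
#' @param result An `mr_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
render_report <- function(result, out_dir) {
  stopifnot(inherits(result, "mr_pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- tsv(result$report, "report.tsv")
  if (!is.null(result$estimates)) {
    forest <- result$estimates[, c("exposure_id", "method", "nsnp", "beta",
                                   "se", "ci_low", "ci_high", "pval",
                                   "or_ci_text")]
    paths <- c(paths, tsv(forest, "forest.tsv"))
    pmat <- stats::reshape(
      result$estimates[, c("exposure_id", "method", "pval")],
      idvar = "exposure_id", timevar = "method", direction = "wide")
    names(pmat) <- sub("^pval\\.", "p_", names(pmat))
    alpha <- result$config$alpha
    for (m in setdiff(names(pmat), "exposure_id")) {
      pmat[[paste0(m, "_sig")]] <- !is.na(pmat[[m]]) & pmat[[m]] < alpha
    }
    paths <- c(paths, tsv(pmat, "pvalue_matrix.tsv"))
  }
  if (!is.null(result$loo)) {
    paths <- c(paths, tsv(result$loo, "leave_one_out.tsv"))
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(alpha = result$config$alpha,
         seed = result$config$seed,
         effects_model = result$config$effects_model,
         thresholds = list(pval = result$config$pval_threshold,
                           clump_r2 = result$config$clump_r2,
                           clump_kb = result$config$clump_kb,
                           f = result$config$f_threshold),
         assumptions = paste(
           "palindrome handling and allele harmonization follow common",
           "two-sample MR practice (EAF margin",
           result$config$palindrome_eaf_margin, "around 0.5)"),
         report = result$report),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, summary_path))
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat(sprintf("<mr_pipeline_result> %d exposure(s), %d significant\n",
              nrow(x$report), sum(x$report$significant, na.rm = TRUE)))
  print(x$report[, c("exposure_id", "nsnp", "ivw_p", "or_ci_text",
                     "significant", "status")], row.names = FALSE)
  invisible(x)
}
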