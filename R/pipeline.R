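#' Run one exposure -> outcome MR analysis end to end
#'
#' Executes the full stage chain: exposure-association filter, LD clumping
#' (when LD information is supplied), harmonization (palindromic-SNP
#' removal), strength/outcome-association/confounder filters, Steiger
#' directionality filter, causal estimation and the sensitivity battery.
#' If MR-PRESSO or radial MR flags outliers, they are removed and
#' estimation plus sensitivity are re-run exactly once; both passes are
#' reported, with the outlier-free pass as the headline result. Every SNP
#' entering the analysis appears exactly once in the audit log or among
#' the surviving instruments.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param criteria an [mr_criteria] object.
#' @param direction `"forward"` or `"reverse"` (label only; thresholds
#'   come from `criteria`).
#' @param methods estimators to run, forwarded to [mr_estimates].
#' @param seed integer seed covering the weighted-median bootstrap and
#'   MR-PRESSO simulations.
#' @param ld optional [ld_info]; when `NULL`, clumping is skipped (the
#'   instruments are assumed independent, e.g. synthetic post-clumping
#'   panels).
#' @param presso_n_sim MR-PRESSO replicates.
#' @param outlier_rerun run the single outlier-removal re-execution when
#'   outliers are flagged.
#' @return A `pair_result`. When fewer than 2 instruments survive, the
#'   result carries `extra$status = "not_estimable"` and empty estimates
#'   rather than failing.
#' @export
run_pair <- function(exposure, outcome, criteria = mr_criteria(),
                     direction = "forward",
                     methods = c("ivw", "egger", "wmedian", "cml_ma"),
                     seed = 1, ld = NULL, presso_n_sim = 1000,
                     outlier_rerun = TRUE) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"),
            inherits(criteria, "mr_criteria"))
  audit <- exclusion_row(character(0), character(0), character(0))
  n_input <- nrow(exposure$records)

  sel <- filter_by_exposure_p(exposure, criteria$p_exposure_max)
  dropped <- setdiff(exposure$records$snp_id, sel$records$snp_id)
  if (length(dropped)) {
    audit <- rbind(audit, exclusion_row(dropped, "exposure_p",
                                        "exposure_p_above_threshold"))
  }
  if (!is.null(ld) && nrow(sel$records) > 0) {
    clumped <- ld_clump(sel, ld, r2_max = criteria$clump_r2_max,
                        window_kb = criteria$clump_window_kb)
    dropped <- setdiff(sel$records$snp_id, clumped$records$snp_id)
    if (length(dropped)) {
      audit <- rbind(audit, exclusion_row(dropped, "clump", "ld_clumped"))
    }
    sel <- clumped
  }
  not_estimable <- function(status) {
    pair_result(exposure$trait_label, outcome$trait_label, direction,
                estimates = list(), sensitivity = NULL, hset = NULL,
                extra = list(status = status, audit_log = audit,
                             n_input = n_input, criteria = criteria,
                             seed = seed))
  }
  if (nrow(sel$records) == 0) return(not_estimable("not_estimable"))

  hset <- tryCatch(harmonize_set(sel, outcome),
                   mrkit_empty_instruments = function(e) e)
  if (inherits(hset, "condition")) {
    audit <- rbind(audit, hset$exclusion_log)
    return(not_estimable("not_estimable"))
  }
  hset <- apply_filters(hset, criteria)
  hset <- steiger_filter(hset)
  audit <- rbind(audit, hset$exclusion_log)
  hset$exclusion_log <- audit
  if (nrow(hset$pairs) < 2) {
    res <- not_estimable("not_estimable")
    res$hset <- hset
    res$n_snp_final <- nrow(hset$pairs)
    return(res)
  }

  run_once <- function(h, s) {
    list(estimates = mr_estimates(h, methods = methods, seed = s),
         sensitivity = sensitivity_report(h, seed = s + 1L,
                                          presso_n_sim = presso_n_sim))
  }
  pass1 <- run_once(hset, seed)
  outliers <- unique(c(
    if (!is.null(pass1$sensitivity$presso))
      pass1$sensitivity$presso$outlier_ids,
    if (!is.null(pass1$sensitivity$radial))
      pass1$sensitivity$radial$outlier_ids))
  final_hset <- hset
  final <- pass1
  reran <- FALSE
  if (outlier_rerun && length(outliers) > 0 &&
      nrow(hset$pairs) - length(outliers) >= 2) {
    final_hset <- subset_hset(hset, !(hset$pairs$snp_id %in% outliers),
                              stage = "outlier", reason = "outlier")
    final <- run_once(final_hset, seed + 1000L)
    reran <- TRUE
  }
  pair_result(exposure$trait_label, outcome$trait_label, direction,
              estimates = final$estimates,
              sensitivity = final$sensitivity, hset = final_hset,
              extra = list(status = "ok",
                           audit_log = final_hset$exclusion_log,
                           n_input = n_input, criteria = criteria,
                           seed = seed, outliers_removed = outliers,
                           outlier_rerun_done = reran,
                           first_pass = if (reran) pass1 else NULL))
}

#' Run the full bidirectional analysis
#'
#' Analyses one focal trait against a panel of partner traits in both
#' directions: forward (focal trait as exposure, each partner as outcome)
#' and reverse (each partner as exposure, focal trait as outcome), with
#' independently specified selection criteria per direction (a relaxed
#' exposure threshold is conventional in the reverse direction when few
#' SNPs reach genome-wide significance). Benjamini-Hochberg FDR is applied
#' to the IVW p-values within each direction.
#'
#' @param focal a [summary_stats] object (the bidirectional hub trait).
#' @param partners named list of [summary_stats] objects.
#' @param criteria_forward,criteria_reverse [mr_criteria] per direction.
#' @param methods,presso_n_sim,outlier_rerun forwarded to [run_pair].
#' @param seed base seed; pair i uses `seed + i` (forward) and
#'   `seed + 100 + i` (reverse).
#' @param ld optional [ld_info] shared by all pairs.
#' @return The list produced by [assemble_report] over all pair results,
#'   plus `pair_results`.
#' @export
run_bidirectional <- function(focal, partners,
                              criteria_forward = mr_criteria(
                                p_exposure_max = 5e-8),
                              criteria_reverse = mr_criteria(
                                p_exposure_max = 5e-6),
                              methods = c("ivw", "egger", "wmedian",
                                          "cml_ma"),
                              seed = 1, ld = NULL, presso_n_sim = 1000,
                              outlier_rerun = TRUE) {
  stopifnot(inherits(focal, "summary_stats"), length(partners) >= 1)
  if (is.null(names(partners)) || any(!nzchar(names(partners)))) {
    stop("partners must be a named list", call. = FALSE)
  }
  results <- list()
  for (i in seq_along(partners)) {
    results[[length(results) + 1L]] <-
      run_pair(focal, partners[[i]], criteria = criteria_forward,
               direction = "forward", methods = methods,
               seed = seed + i, ld = ld, presso_n_sim = presso_n_sim,
               outlier_rerun = outlier_rerun)
  }
  for (i in seq_along(partners)) {
    results[[length(results) + 1L]] <-
      run_pair(partners[[i]], focal, criteria = criteria_reverse,
               direction = "reverse", methods = methods,
               seed = seed + 100L + i, ld = ld,
               presso_n_sim = presso_n_sim,
               outlier_rerun = outlier_rerun)
  }
  rep <- assemble_report(results,
                         expected_per_direction = length(partners))
  rep$pair_results <- rep$results
  rep
}

#' Write the report tables and audit logs of an analysis to a directory
#'
#' Emits `estimates.tsv` and `sensitivity.tsv` (full precision),
#' `estimates_rounded.tsv` (publication precision), one exclusion/audit
#' table per pair, and per-pair radial and leave-one-out tables. Output is
#' deterministic: identical inputs and seeds give byte-identical files.
#'
#' @param report the list returned by [run_bidirectional] (or
#'   [assemble_report]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_files <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tab, name) {
    path <- file.path(dir, name)
    write_table(tab, path)
    files <<- c(files, path)
  }
  if (nrow(report$estimates) > 0) {
    emit(report$estimates, "estimates.tsv")
    emit(round_report(report$estimates), "estimates_rounded.tsv")
  }
  if (!is.null(report$sensitivity) && nrow(report$sensitivity) > 0) {
    emit(report$sensitivity, "sensitivity.tsv")
  }
  for (res in report$results) {
    tag <- sprintf("%s_%s_to_%s", res$direction,
                   gsub("[^A-Za-z0-9]+", "_", res$exposure_label),
                   gsub("[^A-Za-z0-9]+", "_", res$outcome_label))
    log <- res$extra$audit_log
    if (!is.null(log) && nrow(log) > 0) {
      emit(log, sprintf("audit_%s.tsv", tag))
    }
    if (!is.null(res$sensitivity$radial)) {
      emit(res$sensitivity$radial$q, sprintf("radial_%s.tsv", tag))
    }
    if (!is.null(res$sensitivity$loo)) {
      emit(res$sensitivity$loo, sprintf("loo_%s.tsv", tag))
    }
  }
  invisible(files)
}
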