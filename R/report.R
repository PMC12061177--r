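#' Benjamini-Hochberg step-up FDR adjustment
#'
#' For raw p-values p(1) <= ... <= p(m), the adjusted value at rank i is
#' min over k >= i of min(1, p(k) * m / k), returned in the input order.
#' Controls the expected proportion of false discoveries at the reported
#' level.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("bh_adjust: p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  o <- order(pvals)
  ranked <- pvals[o] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param beta effect on the log-odds scale.
#' @param se standard error of `beta` (> 0).
#' @return A list with `or`, `ci_low`, `ci_high` where OR = exp(beta) and
#'   the CI is exp(beta +/- 1.96 * se).
#' @export
effect_to_or <- function(beta, se) {
  if (any(se <= 0)) stop("effect_to_or: se must be positive", call. = FALSE)
  list(or = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Bundle one exposure-outcome analysis into a pair result
#'
#' @param exposure_label,outcome_label trait labels.
#' @param direction `"forward"` or `"reverse"`.
#' @param estimates named list of `mr_estimate` objects (from
#'   [mr_estimates]).
#' @param sensitivity a `sensitivity_report` (or NULL).
#' @param hset the final `harmonized_set` used (carries the exclusion log).
#' @param extra optional named list of additional metadata.
#' @return A list of class `pair_result`.
#' @export
pair_result <- function(exposure_label, outcome_label, direction,
                        estimates, sensitivity = NULL, hset = NULL,
                        extra = list()) {
  stopifnot(direction %in% c("forward", "reverse"))
  raw_p_ivw <- if (!is.null(estimates$ivw)) estimates$ivw$pval else NA_real_
  structure(list(
    exposure_label = exposure_label, outcome_label = outcome_label,
    direction = direction, estimates = estimates,
    sensitivity = sensitivity, hset = hset,
    n_snp_final = if (!is.null(hset)) nrow(hset$pairs) else NA_integer_,
    raw_p_ivw = raw_p_ivw, fdr_p_ivw = NA_real_, extra = extra
  ), class = "pair_result")
}

estimate_row <- function(res, method, est) {
  or <- effect_to_or(est$beta, est$se)
  data.frame(
    exposure = res$exposure_label, outcome = res$outcome_label,
    direction = res$direction, method = method, n_snp = est$n_snp,
    beta = est$beta, se = est$se, or = or$or, or_ci_low = or$ci_low,
    or_ci_high = or$ci_high, pval = est$pval, stringsAsFactors = FALSE
  )
}

#' Assemble forest-style and sensitivity tables with per-direction FDR
#'
#' Applies Benjamini-Hochberg FDR to the IVW p-values within each
#' direction (the forward analyses form one family, the reverse analyses
#' another), and emits one forest-style estimate table and one sensitivity
#' table per direction. A pair is called significant when both its raw IVW
#' p and its FDR-adjusted p are below 0.05. Other estimators' p-values are
#' reported unadjusted.
#'
#' @param results list of `pair_result` objects.
#' @param expected_per_direction expected family size per direction (a
#'   warning is raised if fewer are present; FDR then uses those present).
#' @return A list with `estimates` (data.frame over all pairs and methods,
#'   with `fdr_p` and `significant` filled on IVW rows), `sensitivity`
#'   (one row per pair), and the input `results` with `fdr_p_ivw` filled.
#' @export
assemble_report <- function(results, expected_per_direction = NULL) {
  if (length(results) == 0) {
    return(list(estimates = data.frame(), sensitivity = data.frame(),
                results = results))
  }
  stopifnot(all(vapply(results, inherits, TRUE, "pair_result")))
  key <- vapply(results, function(r) paste(r$direction, r$outcome_label,
                                           r$exposure_label), "")
  if (anyDuplicated(key)) {
    stop("duplicate (direction, exposure, outcome) in results",
         call. = FALSE)
  }
  dirs <- vapply(results, `[[`, "", "direction")
  for (d in unique(dirs)) {
    idx <- which(dirs == d)
    raw <- vapply(results[idx], `[[`, 0, "raw_p_ivw")
    ok <- !is.na(raw)
    if (!is.null(expected_per_direction) &&
        sum(ok) < expected_per_direction) {
      warning(sprintf(
        "direction %s: FDR family has %d of %d expected members", d,
        sum(ok), expected_per_direction), call. = FALSE)
    }
    if (any(ok)) {
      adj <- bh_adjust(raw[ok])
      for (k in seq_along(which(ok))) {
        results[[idx[which(ok)[k]]]]$fdr_p_ivw <- adj[k]
      }
    }
  }
  est_rows <- list()
  sens_rows <- list()
  for (res in results) {
    for (m in names(res$estimates)) {
      row <- estimate_row(res, m, res$estimates[[m]])
      row$fdr_p <- if (m == "ivw") res$fdr_p_ivw else NA_real_
      row$significant <- if (m == "ivw") {
        !is.na(res$raw_p_ivw) && res$raw_p_ivw < 0.05 &&
          !is.na(res$fdr_p_ivw) && res$fdr_p_ivw < 0.05
      } else NA
      est_rows[[length(est_rows) + 1L]] <- row
    }
    s <- res$sensitivity
    sens_rows[[length(sens_rows) + 1L]] <- data.frame(
      exposure = res$exposure_label, outcome = res$outcome_label,
      direction = res$direction,
      n_snp = res$n_snp_final,
      p_q_egger = if (!is.null(s$q_egger)) s$q_egger$pval else NA_real_,
      p_q_ivw = if (!is.null(s$q_ivw)) s$q_ivw$pval else NA_real_,
      p_egger_intercept = if (!is.null(s$egger_intercept))
        s$egger_intercept$pval else NA_real_,
      p_presso_global = if (!is.null(s$presso)) s$presso$global_p
        else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(estimates = do.call(rbind, est_rows),
       sensitivity = do.call(rbind, sens_rows),
       results = results)
}

#' Round a report table to publication precision
#'
#' Rounds OR, CI and p columns to 3 decimals for display; the
#' machine-readable tables keep full precision.
#'
#' @param tab a data.frame from [assemble_report].
#' @return The rounded data.frame.
#' @export
round_report <- function(tab) {
  for (col in intersect(c("or", "or_ci_low", "or_ci_high", "pval", "fdr_p",
                          "p_q_egger", "p_q_ivw", "p_egger_intercept",
                          "p_presso_global"), names(tab))) {
    tab[[col]] <- round(tab[[col]], 3)
  }
  tab
}
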