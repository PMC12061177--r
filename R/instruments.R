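#' Instrument-selection criteria
#'
#' Bundles the thresholds of the instrument-selection filter chain. Defaults
#' follow common two-sample MR practice for a well-powered exposure GWAS:
#' genome-wide significance 5e-8 for the exposure association, LD clumping at
#' r-squared < 0.001 within 10,000 kb, per-SNP F-statistic floor of 10,
#' removal of instruments strongly associated with the outcome (p < 5e-5),
#' and an optional list of SNPs tied to known confounders. For
#' poorly-powered exposures a relaxed `p_exposure_max` (e.g. 5e-6) is
#' conventional.
#'
#' @param p_exposure_max exposure association p-value threshold (keep p <
#'   this value).
#' @param clump_r2_max LD r-squared ceiling for clumping, in [0, 1).
#' @param clump_window_kb clumping window in kilobases.
#' @param f_min weak-instrument floor on the per-SNP F-statistic.
#' @param p_outcome_min outcome-association floor: instruments with outcome
#'   p-value below this are removed.
#' @param exclusion_list character vector of SNP ids associated with
#'   potential confounders.
#' @return A list of class `mr_criteria`.
#' @export
mr_criteria <- function(p_exposure_max = 5e-8, clump_r2_max = 0.001,
                        clump_window_kb = 10000, f_min = 10,
                        p_outcome_min = 5e-5,
                        exclusion_list = character(0)) {
  stopifnot(p_exposure_max > 0, clump_r2_max >= 0, clump_r2_max < 1,
            clump_window_kb > 0, f_min > 0, p_outcome_min > 0)
  structure(list(p_exposure_max = p_exposure_max, clump_r2_max = clump_r2_max,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 p_outcome_min = p_outcome_min,
                 exclusion_list = as.character(exclusion_list)),
            class = "mr_criteria")
}

#' Linkage-disequilibrium information for a SNP panel
#'
#' Holds pairwise r-squared values and per-SNP genomic positions used by
#' [ld_clump]. The r-squared source is either a square matrix (with SNP ids
#' as dimnames) or a long-format data.frame with columns `snp_a`, `snp_b`,
#' `r2`; unlisted pairs are treated as r-squared 0 (unlinked).
#'
#' @param r2 square numeric matrix with SNP-id dimnames, or a long-format
#'   data.frame (`snp_a`, `snp_b`, `r2`).
#' @param positions data.frame with columns `snp_id`, `chrom`, `bp`.
#' @return An object of class `ld_info` with a `lookup(a, b)` closure.
#' @export
ld_info <- function(r2, positions) {
  stopifnot(all(c("snp_id", "chrom", "bp") %in% names(positions)))
  positions <- as.data.frame(positions)
  if (anyDuplicated(positions$snp_id)) {
    stop("duplicate snp_id in positions", call. = FALSE)
  }
  if (is.matrix(r2)) {
    if (is.null(rownames(r2)) || is.null(colnames(r2)) ||
        !identical(rownames(r2), colnames(r2))) {
      stop("r2 matrix needs identical snp-id row and column names",
           call. = FALSE)
    }
    if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
      stop("r2 values must lie in [0, 1]", call. = FALSE)
    }
    tab <- r2
    lookup <- function(a, b) {
      if (a %in% rownames(tab) && b %in% rownames(tab)) tab[a, b] else 0
    }
  } else {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(r2)))
    if (any(r2$r2 < 0 | r2$r2 > 1, na.rm = TRUE)) {
      stop("r2 values must lie in [0, 1]", call. = FALSE)
    }
    key <- c(paste(r2$snp_a, r2$snp_b, sep = "\r"),
             paste(r2$snp_b, r2$snp_a, sep = "\r"))
    val <- c(r2$r2, r2$r2)
    env <- new.env(parent = emptyenv())
    for (i in seq_along(key)) assign(key[i], val[i], envir = env)
    lookup <- function(a, b) {
      if (a == b) return(1)
      v <- mget(paste(a, b, sep = "\r"), envir = env,
                ifnotfound = list(0))[[1]]
      v
    }
  }
  structure(list(positions = positions, lookup = lookup), class = "ld_info")
}

#' Filter summary statistics by exposure association p-value
#'
#' @param ss a [summary_stats] object.
#' @param p_max keep records with `pval < p_max`; order preserved.
#' @return A [summary_stats] object (possibly with zero records is an error
#'   at construction, so an empty result is returned as a records-preserving
#'   subset; callers decide how to treat emptiness).
#' @export
filter_by_exposure_p <- function(ss, p_max) {
  stopifnot(inherits(ss, "summary_stats"))
  keep <- ss$records$pval < p_max
  out <- ss
  out$records <- ss$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending exposure p-value (ties broken by ascending
#' `snp_id`), repeatedly takes the best remaining SNP as an index SNP and
#' removes every other remaining SNP on the same chromosome within
#' `window_kb` of it whose pairwise r-squared with the index is at least
#' `r2_max`. The window never spans chromosomes.
#'
#' @param ss a [summary_stats] object.
#' @param ld an [ld_info] object covering every SNP in `ss`.
#' @param r2_max r-squared ceiling: SNPs with r2 >= this value to an index
#'   SNP are clumped away.
#' @param window_kb clumping distance in kilobases.
#' @return A [summary_stats] object containing the index SNPs, in the
#'   original record order.
#' @export
ld_clump <- function(ss, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(ss, "summary_stats"), inherits(ld, "ld_info"))
  rec <- ss$records
  pos_idx <- match(rec$snp_id, ld$positions$snp_id)
  if (anyNA(pos_idx)) {
    stop("SNPs missing from LD position table: ",
         paste(utils::head(rec$snp_id[is.na(pos_idx)], 10), collapse = ", "),
         call. = FALSE)
  }
  chrom <- ld$positions$chrom[pos_idx]
  bp <- as.numeric(ld$positions$bp[pos_idx])
  ord <- order(rec$pval, rec$snp_id)
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & chrom == chrom[i] &
                    abs(bp - bp[i]) <= window_kb * 1000)
    for (j in cand) {
      if (ld$lookup(rec$snp_id[i], rec$snp_id[j]) >= r2_max) {
        alive[j] <- FALSE
      }
    }
  }
  out <- ss
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Per-SNP instrument strength: variance explained and F-statistic
#'
#' Computes the proportion of exposure variance explained by a variant,
#' R2 = 2 * EAF * (1 - EAF) * beta^2, and the corresponding per-instrument
#' F-statistic F = R2 * (N - 2) / (1 - R2). Instruments with F below 10 are
#' conventionally considered weak.
#'
#' @param beta per-allele effect estimate.
#' @param eaf effect-allele frequency (required; missing frequency makes the
#'   strength undefined).
#' @param n sample size (>= 3).
#' @return A list with `r2` and `f_stat`, or `NULL` when `eaf` is missing.
#' @export
instrument_strength <- function(beta, eaf, n) {
  if (is.na(eaf)) return(NULL)
  if (is.na(n) || n < 3) stop("instrument_strength needs n >= 3",
                              call. = FALSE)
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  r2 <- min(r2, 1 - 1e-12)  # guard: r2 must stay below 1
  list(r2 = r2, f_stat = r2 * (n - 2) / (1 - r2))
}

#' Apply strength, outcome-association and confounder filters
#'
#' Excludes harmonized pairs that are weak instruments (per-SNP F below
#' `criteria$f_min`, or missing exposure EAF so the F-statistic is
#' undefined), pairs strongly associated with the outcome
#' (`pval_out < criteria$p_outcome_min`), and pairs on the confounder
#' exclusion list. Exclusion reasons: `no_eaf`, `weak_instrument`,
#' `outcome_associated`, `confounder`. Idempotent: a second application
#' changes nothing.
#'
#' @param hset a `harmonized_set`.
#' @param criteria an [mr_criteria] object.
#' @return The filtered `harmonized_set` with the exclusion log extended.
#' @export
apply_filters <- function(hset, criteria = mr_criteria()) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs
  n <- nrow(p)
  reason <- rep(NA_character_, n)
  f_stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- instrument_strength(p$beta_exp[i], p$eaf_exp[i], p$n_exp[i])
    if (is.null(s)) {
      reason[i] <- "no_eaf"
    } else {
      f_stat[i] <- s$f_stat
      if (s$f_stat < criteria$f_min) reason[i] <- "weak_instrument"
    }
  }
  hit <- is.na(reason) & p$pval_out < criteria$p_outcome_min
  reason[hit] <- "outcome_associated"
  hit <- is.na(reason) & p$snp_id %in% criteria$exclusion_list
  reason[hit] <- "confounder"
  subset_hset(hset, is.na(reason), stage = "instrument_filters",
              reason = NULL, reasons = reason)
}

#' Steiger directionality test and filter
#'
#' For each harmonized pair, computes the variance explained on each side
#' (R2 = 2 * EAF * (1 - EAF) * beta^2) and tests whether the instrument
#' explains significantly more variance in the exposure than in the outcome.
#' The one-sided test compares the Fisher-z transformed absolute correlations
#' r = sqrt(R2): z = (atanh(r_exp) - atanh(r_out)) /
#' sqrt(1/(n_exp - 3) + 1/(n_out - 3)). A SNP's direction is TRUE iff
#' r2_exp > r2_out and the one-sided p-value is below `alpha`.
#'
#' `steiger_filter` removes FALSE-direction SNPs (reason `steiger_false`);
#' SNPs with a missing EAF on either side cannot be tested and pass with a
#' warning. `steiger_test` reports the per-SNP table, and in `pooled` mode a
#' single set-level test using pooled correlations sqrt(sum(R2)) per side
#' with the median sample size on each side.
#'
#' @param hset a `harmonized_set`.
#' @param alpha one-sided significance level for calling a TRUE direction.
#' @param mode `"per_snp"` (the filter's basis) or `"pooled"` (one set-level
#'   summary test).
#' @return `steiger_test`: a data.frame (per_snp) or one-row data.frame
#'   (pooled) with r2 on both sides, the z statistic, one-sided p and the
#'   direction call. `steiger_filter`: the filtered `harmonized_set`.
#' @export
steiger_test <- function(hset, alpha = 0.05,
                         mode = c("per_snp", "pooled")) {
  stopifnot(inherits(hset, "harmonized_set"))
  mode <- match.arg(mode)
  p <- hset$pairs
  r2_exp <- 2 * p$eaf_exp * (1 - p$eaf_exp) * p$beta_exp^2
  r2_out <- 2 * p$eaf_out * (1 - p$eaf_out) * p$beta_out^2
  if (mode == "pooled") {
    ok <- !is.na(r2_exp) & !is.na(r2_out)
    rx <- sqrt(min(sum(r2_exp[ok]), 1 - 1e-12))
    ry <- sqrt(min(sum(r2_out[ok]), 1 - 1e-12))
    nx <- stats::median(p$n_exp[ok])
    ny <- stats::median(p$n_out[ok])
    z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
    pv <- stats::pnorm(z, lower.tail = FALSE)
    return(data.frame(r2_exp = rx^2, r2_out = ry^2, z = z, pval = pv,
                      direction_true = rx^2 > ry^2 & pv < alpha,
                      n_snp_used = sum(ok)))
  }
  z <- (atanh(sqrt(pmin(r2_exp, 1 - 1e-12))) -
          atanh(sqrt(pmin(r2_out, 1 - 1e-12)))) /
    sqrt(1 / (p$n_exp - 3) + 1 / (p$n_out - 3))
  pv <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(snp_id = p$snp_id, r2_exp = r2_exp, r2_out = r2_out, z = z,
             pval = pv,
             direction_true = !is.na(z) & r2_exp > r2_out & pv < alpha,
             testable = !is.na(r2_exp) & !is.na(r2_out),
             stringsAsFactors = FALSE)
}

#' @rdname steiger_test
#' @export
steiger_filter <- function(hset, alpha = 0.05) {
  st <- steiger_test(hset, alpha = alpha, mode = "per_snp")
  if (any(!st$testable)) {
    warning(sum(!st$testable),
            " SNP(s) lack EAF on one side; Steiger direction untestable,",
            " passed through", call. = FALSE)
  }
  keep <- !st$testable | st$direction_true
  subset_hset(hset, keep, stage = "steiger", reason = "steiger_false")
}
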