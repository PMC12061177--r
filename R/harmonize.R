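#' @rdname harmonize_pair
#' @export
classify_palindrome <- function(effect_allele, other_allele) {
  if (!(effect_allele %in% VALID_BASES) || !(other_allele %in% VALID_BASES) ||
      effect_allele == other_allele) {
    stop("alleles must be two distinct single bases among A/C/G/T",
         call. = FALSE)
  }
  complement_base(effect_allele) == other_allele
}

complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

empty_harmonized_pairs <- function() {
  data.frame(snp_id = character(0),
             beta_exp = double(0), se_exp = double(0), eaf_exp = double(0),
             pval_exp = double(0), n_exp = integer(0),
             beta_out = double(0), se_out = double(0), eaf_out = double(0),
             pval_out = double(0), n_out = integer(0),
             flipped = logical(0), stringsAsFactors = FALSE)
}

exclusion_row <- function(snp_id, stage, reason) {
  data.frame(snp_id = snp_id, stage = stage, reason = reason,
             stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome SNP record pair onto a common effect allele
#'
#' The exposure orientation is taken as reference. If the outcome alleles
#' match directly the pair is kept unchanged; if they are swapped the outcome
#' effect is negated and its effect-allele frequency reflected (1 - eaf); if
#' they are the strand complements (direct or swapped) the outcome is recoded
#' to the exposure strand first and the same rule applied. Palindromic pairs
#' (A/T, C/G) are excluded outright because their strand cannot be resolved;
#' irreconcilable allele sets are excluded as mismatches.
#'
#' @param exp_rec,out_rec single-row data.frames (or one-row lists) with the
#'   canonical summary-statistic fields, sharing `snp_id`.
#' @return For `harmonize_pair`, a list with either `pair` (one-row
#'   harmonized data.frame) or `exclusion` (snp_id/stage/reason row).
#' @export
harmonize_pair <- function(exp_rec, out_rec) {
  exp_rec <- as.list(exp_rec)
  out_rec <- as.list(out_rec)
  if (!identical(as.character(exp_rec$snp_id), as.character(out_rec$snp_id))) {
    stop("harmonize_pair: snp_id mismatch (", exp_rec$snp_id, " vs ",
         out_rec$snp_id, ")", call. = FALSE)
  }
  id <- as.character(exp_rec$snp_id)
  e1 <- exp_rec$effect_allele; e2 <- exp_rec$other_allele
  o1 <- out_rec$effect_allele; o2 <- out_rec$other_allele
  if (classify_palindrome(e1, e2) || classify_palindrome(o1, o2)) {
    return(list(exclusion = exclusion_row(id, "harmonize", "palindromic")))
  }
  # try outcome as-is, then on the complementary strand
  flipped <- NA
  for (strand in 1:2) {
    if (strand == 2) {
      o1 <- unname(complement_base(o1))
      o2 <- unname(complement_base(o2))
    }
    if (o1 == e1 && o2 == e2) { flipped <- FALSE; break }
    if (o1 == e2 && o2 == e1) { flipped <- TRUE; break }
  }
  if (is.na(flipped)) {
    return(list(exclusion = exclusion_row(id, "harmonize", "allele_mismatch")))
  }
  beta_out <- out_rec$beta
  eaf_out <- out_rec$eaf
  if (flipped) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
  }
  pair <- data.frame(
    snp_id = id,
    beta_exp = exp_rec$beta, se_exp = exp_rec$se,
    eaf_exp = if (is.null(exp_rec$eaf)) NA_real_ else exp_rec$eaf,
    pval_exp = exp_rec$pval, n_exp = as.integer(exp_rec$n),
    beta_out = beta_out, se_out = out_rec$se, eaf_out = eaf_out,
    pval_out = out_rec$pval, n_out = as.integer(out_rec$n),
    flipped = flipped, stringsAsFactors = FALSE
  )
  list(pair = pair)
}

#' Harmonize a set of instruments against an outcome study
#'
#' Looks up each instrument SNP in the outcome summary statistics and places
#' exposure and outcome effects on a common effect allele via
#' [harmonize_pair]. Instruments absent from the outcome are excluded with
#' reason `missing_in_outcome`. Every input SNP ends up exactly once: either
#' in `pairs` or in `exclusion_log`.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param snp_ids instrument identifiers (must be a subset of the exposure's
#'   SNP ids). Defaults to all exposure SNPs.
#' @return A `harmonized_set`: list with `pairs` (data.frame of harmonized
#'   exposure/outcome rows), `exclusion_log` (snp_id/stage/reason) and the
#'   two trait labels.
#' @export
harmonize_set <- function(exposure, outcome, snp_ids = NULL) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  if (is.null(snp_ids)) snp_ids <- exposure$records$snp_id
  missing_exp <- setdiff(snp_ids, exposure$records$snp_id)
  if (length(missing_exp) > 0) {
    stop("instrument ids absent from exposure: ",
         paste(utils::head(missing_exp, 5), collapse = ", "), call. = FALSE)
  }
  exp_rec <- exposure$records[match(snp_ids, exposure$records$snp_id), ,
                              drop = FALSE]
  out_idx <- match(snp_ids, outcome$records$snp_id)

  pairs <- list()
  exclusions <- list()
  for (i in seq_along(snp_ids)) {
    if (is.na(out_idx[i])) {
      exclusions[[length(exclusions) + 1L]] <-
        exclusion_row(snp_ids[i], "harmonize", "missing_in_outcome")
      next
    }
    res <- harmonize_pair(exp_rec[i, ], outcome$records[out_idx[i], ])
    if (!is.null(res$pair)) {
      pairs[[length(pairs) + 1L]] <- res$pair
    } else {
      exclusions[[length(exclusions) + 1L]] <- res$exclusion
    }
  }
  hset <- structure(
    list(
      pairs = if (length(pairs)) do.call(rbind, pairs)
              else empty_harmonized_pairs(),
      exclusion_log = if (length(exclusions)) do.call(rbind, exclusions)
                      else exclusion_row(character(0), character(0),
                                         character(0)),
      exposure_label = exposure$trait_label,
      outcome_label = outcome$trait_label
    ),
    class = "harmonized_set"
  )
  if (nrow(hset$pairs) == 0) {
    cond <- structure(
      class = c("mrkit_empty_instruments", "error", "condition"),
      list(message = sprintf(
             "no instruments survive harmonization (%s -> %s); see exclusion_log",
             exposure$trait_label, outcome$trait_label),
           call = sys.call(-1), exclusion_log = hset$exclusion_log))
    stop(cond)
  }
  rownames(hset$pairs) <- NULL
  hset
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d pairs, %d excluded\n",
              x$exposure_label, x$outcome_label, nrow(x$pairs),
              nrow(x$exclusion_log)))
  invisible(x)
}

#' @export
nsnp.harmonized_set <- function(x) nrow(x$pairs)

# rebuild a harmonized_set with a pair subset, appending exclusions
subset_hset <- function(hset, keep, stage, reason,
                        reasons = NULL) {
  dropped <- hset$pairs[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    rr <- if (is.null(reasons)) rep(reason, nrow(dropped))
          else reasons[!keep]
    hset$exclusion_log <- rbind(hset$exclusion_log,
                                exclusion_row(dropped$snp_id,
                                              rep(stage, nrow(dropped)), rr))
  }
  hset$pairs <- hset$pairs[keep, , drop = FALSE]
  rownames(hset$pairs) <- NULL
  hset
}
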