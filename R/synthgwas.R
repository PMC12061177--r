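#' Configuration for the synthetic GWAS summary-statistic generator
#'
#' Describes one simulated exposure/outcome study pair under the
#' structural model beta_out_j = theta * beta_exp_j + r_j, where r_j is a
#' per-SNP direct (pleiotropic) effect on the outcome. Defaults describe a
#' post-clumping panel of independent common variants from two large
#' biobank-scale GWAS.
#'
#' @param n_snp number of instruments.
#' @param n_exp,n_out GWAS sample sizes (>= 100).
#' @param theta true causal effect of the exposure on the outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects with mean
#'   zero), `"directional"` (mean `pleiotropy_mean`), or
#'   `"inside_violating"` (direct effects correlated with the instrument
#'   strengths, violating the InSIDE assumption).
#' @param pleiotropy_sd spread of per-SNP direct effects.
#' @param pleiotropy_mean mean direct effect (directional mode).
#' @param prop_invalid fraction of SNPs carrying a direct effect, in
#'   [0, 1].
#' @param eaf_range allele-frequency interval (subset of (0, 1)).
#' @param beta_exp_sd spread of the true instrument effects on the
#'   exposure.
#' @param f_floor optional per-SNP F-statistic floor; true instrument
#'   effects are resampled until the F computed from the true effect, the
#'   allele frequency and `n_exp` reaches it.
#' @param palindromic_frac fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs.
#' @param strand_flip_frac fraction of non-palindromic SNPs whose outcome
#'   records are written on the complementary strand.
#' @param swap_frac fraction of non-palindromic SNPs whose outcome records
#'   swap effect and other allele (with the effect sign and allele
#'   frequency reflected accordingly).
#' @param ld_block_size instruments per LD block; blocks of size > 1 place
#'   SNPs within 50 kb of each other with pairwise r-squared
#'   `ld_block_r2`, solely to exercise clumping.
#' @param ld_block_r2 within-block r-squared.
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 50, n_exp = 100000, n_out = 100000,
                       theta = 0, pleiotropy_mode = c("none", "balanced",
                                                      "directional",
                                                      "inside_violating"),
                       pleiotropy_sd = 0.05, pleiotropy_mean = 0,
                       prop_invalid = 0, eaf_range = c(0.1, 0.9),
                       beta_exp_sd = 0.05, f_floor = NULL,
                       palindromic_frac = 0, strand_flip_frac = 0,
                       swap_frac = 0, ld_block_size = 1, ld_block_r2 = 0.9,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snp >= 1, n_exp >= 100, n_out >= 100,
            prop_invalid >= 0, prop_invalid <= 1,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            palindromic_frac >= 0, palindromic_frac <= 1,
            strand_flip_frac >= 0, strand_flip_frac <= 1,
            swap_frac >= 0, swap_frac <= 1, ld_block_size >= 1)
  if (!is.null(f_floor) && beta_exp_sd <= 0) {
    stop("beta_exp_sd must be positive when an F floor is requested",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic-study presets mirroring the analysed cohorts
#'
#' Returns a [sim_config] whose exposure sample size matches the
#' case+control total of the named study: schizophrenia (PGC3) 130,644;
#' all-cause dementia (acd) 348,676; Alzheimer's disease (ad) 487,511;
#' vascular dementia (vad) 436,182; frontotemporal dementia (ftd) 3,024;
#' dementia with Lewy bodies (dlb) 6,618. All other fields keep the
#' [sim_config] defaults unless overridden through `...`.
#'
#' @param name one of `"schizophrenia"`, `"acd"`, `"ad"`, `"vad"`,
#'   `"ftd"`, `"dlb"`.
#' @param ... overrides forwarded to [sim_config].
#' @return A `sim_config`.
#' @export
preset <- function(name, ...) {
  sizes <- c(schizophrenia = 53386 + 77258,
             acd = 18216 + 330460,
             ad = 85934 + 401577,
             vad = 3116 + 433066,
             ftd = 515 + 2509,
             dlb = 2591 + 4027)
  if (!name %in% names(sizes)) {
    stop("unknown preset: ", name, " (use one of ",
         paste(names(sizes), collapse = ", "), ")", call. = FALSE)
  }
  sim_config(n_exp = unname(sizes[name]), ...)
}

#' @export
preset_n <- function(name) preset(name)$n_exp

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Draws per-SNP allele frequencies uniformly on `eaf_range` and true
#' instrument effects from a half-Normal(0, beta_exp_sd) — effects are
#' reported on the exposure-increasing allele, the orientation under which
#' directional pleiotropy is a meaningful regime — (resampled per SNP until
#' the F-statistic computed from the true effect reaches `f_floor`, when
#' requested). Direct effects r_j are zero for valid SNPs and follow the
#' configured pleiotropy regime otherwise. Observed effects add
#' Normal(0, se_j) noise with the standardized-trait single-SNP
#' approximation se_j = 1/sqrt(2 * eaf_j * (1 - eaf_j) * n); p-values are
#' two-sided normal. Allele pairs are assigned so configurable fractions
#' are palindromic, strand-recoded or allele-swapped in the outcome file.
#'
#' @param cfg a [sim_config].
#' @return A list with `exposure` and `outcome` ([summary_stats]), `truth`
#'   (list: `theta_true`, per-SNP data.frame `snps` with true effects,
#'   direct effects and validity flags), `positions` (snp_id/chrom/bp) and
#'   `ld` (an [ld_info]; identity unless `ld_block_size > 1`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$n_snp
    snp_id <- sprintf("rs%07d", seq_len(L))
    eaf <- stats::runif(L, cfg$eaf_range[1], cfg$eaf_range[2])
    # instruments are reported on the exposure-increasing allele (half-normal
    # true effects); directional pleiotropy is only meaningful relative to a
    # fixed instrument orientation
    beta_true <- abs(stats::rnorm(L, 0, cfg$beta_exp_sd))
    if (!is.null(cfg$f_floor)) {
      for (j in seq_len(L)) {
        repeat {
          s <- instrument_strength(beta_true[j], eaf[j], cfg$n_exp)
          if (s$f_stat >= cfg$f_floor) break
          beta_true[j] <- abs(stats::rnorm(1, 0, cfg$beta_exp_sd))
        }
      }
    }
    n_invalid <- round(cfg$prop_invalid * L)
    valid <- rep(TRUE, L)
    if (n_invalid > 0) valid[sample.int(L, n_invalid)] <- FALSE
    r <- numeric(L)
    if (cfg$pleiotropy_mode != "none" && n_invalid > 0) {
      idx <- which(!valid)
      r[idx] <- switch(cfg$pleiotropy_mode,
        balanced = stats::rnorm(length(idx), 0, cfg$pleiotropy_sd),
        directional = stats::rnorm(length(idx), cfg$pleiotropy_mean,
                                   cfg$pleiotropy_sd),
        inside_violating = {
          # direct effects correlated (rho ~ 0.7) with instrument strength
          z <- beta_true[idx] / max(cfg$beta_exp_sd, 1e-12)
          cfg$pleiotropy_mean + cfg$pleiotropy_sd *
            (0.7 * z + sqrt(1 - 0.49) * stats::rnorm(length(idx)))
        })
    }
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_out)
    beta_exp_hat <- stats::rnorm(L, beta_true, se_exp)
    beta_out_true <- cfg$theta * beta_true + r
    beta_out_hat <- stats::rnorm(L, beta_out_true, se_out)
    pval_exp <- 2 * stats::pnorm(-abs(beta_exp_hat / se_exp))
    pval_out <- 2 * stats::pnorm(-abs(beta_out_hat / se_out))
    pval_exp <- pmax(pval_exp, .Machine$double.xmin)
    pval_out <- pmax(pval_out, .Machine$double.xmin)

    n_pal <- round(cfg$palindromic_frac * L)
    is_pal <- rep(FALSE, L)
    if (n_pal > 0) is_pal[sample.int(L, n_pal)] <- TRUE
    idx_pal <- sample.int(nrow(PALINDROMIC_PAIRS), L, TRUE)
    idx_non <- sample.int(nrow(NONPALINDROMIC_PAIRS), L, TRUE)
    ea <- ifelse(is_pal, PALINDROMIC_PAIRS[idx_pal, 1],
                 NONPALINDROMIC_PAIRS[idx_non, 1])
    oa <- ifelse(is_pal, PALINDROMIC_PAIRS[idx_pal, 2],
                 NONPALINDROMIC_PAIRS[idx_non, 2])

    # outcome-file representation: optionally strand-recoded and/or swapped
    ea_out <- ea; oa_out <- oa
    beta_out_file <- beta_out_hat; eaf_out_file <- eaf
    nonpal <- which(!is_pal)
    flip_idx <- nonpal[stats::runif(length(nonpal)) < cfg$strand_flip_frac]
    ea_out[flip_idx] <- unname(complement_base(ea_out[flip_idx]))
    oa_out[flip_idx] <- unname(complement_base(oa_out[flip_idx]))
    swap_idx <- nonpal[stats::runif(length(nonpal)) < cfg$swap_frac]
    tmp <- ea_out[swap_idx]
    ea_out[swap_idx] <- oa_out[swap_idx]
    oa_out[swap_idx] <- tmp
    beta_out_file[swap_idx] <- -beta_out_file[swap_idx]
    eaf_out_file[swap_idx] <- 1 - eaf_out_file[swap_idx]

    exposure <- summary_stats(
      data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
                 beta = beta_exp_hat, se = se_exp, eaf = eaf,
                 pval = pval_exp, n = as.integer(cfg$n_exp),
                 stringsAsFactors = FALSE),
      trait_label = "synthetic_exposure", provenance = "simulate_pair")
    outcome <- summary_stats(
      data.frame(snp_id = snp_id, effect_allele = ea_out,
                 other_allele = oa_out, beta = beta_out_file, se = se_out,
                 eaf = eaf_out_file, pval = pval_out,
                 n = as.integer(cfg$n_out), stringsAsFactors = FALSE),
      trait_label = "synthetic_outcome", provenance = "simulate_pair")

    # positions: one block per ld_block_size consecutive SNPs; blocks far
    # apart (20 Mb), block members within 50 kb; r2 high within a block
    block <- (seq_len(L) - 1L) %/% cfg$ld_block_size
    chrom <- (block %% 22L) + 1L
    bp <- 1e6 + (block %/% 22L) * 2e7 +
      ((seq_len(L) - 1L) %% cfg$ld_block_size) * 5e4
    positions <- data.frame(snp_id = snp_id, chrom = chrom, bp = bp,
                            stringsAsFactors = FALSE)
    ld_pairs <- if (cfg$ld_block_size > 1) {
      rows <- list()
      for (b in unique(block)) {
        m <- snp_id[block == b]
        if (length(m) > 1) {
          cmb <- utils::combn(m, 2)
          rows[[length(rows) + 1L]] <-
            data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                       r2 = cfg$ld_block_r2, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    } else {
      data.frame(snp_a = character(0), snp_b = character(0),
                 r2 = numeric(0), stringsAsFactors = FALSE)
    }
    truth <- list(
      theta_true = cfg$theta,
      snps = data.frame(snp_id = snp_id, eaf = eaf,
                        beta_exp_true = beta_true, r = r, valid = valid,
                        palindromic = is_pal, stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, truth = truth,
         positions = positions, ld = ld_info(ld_pairs, positions))
  })
}
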