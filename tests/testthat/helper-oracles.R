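# Independent oracles and fixture builders used across the suite.

# Literal step-up BH: for each i, min over k with rank >= i of p(k)*m/k,
# computed by direct enumeration (independent of the package's cummin path).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(k) min(1, p[o[k]] * m / k), 0)
    adj_sorted[i] <- min(vals)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Brute-force greedy clumping oracle: repeatedly scan the full remaining
# list for the highest-priority SNP (smallest p, ties by snp_id), declare
# it an index SNP, drop linked neighbours. Independent of ld_clump's
# bookkeeping.
oracle_clump <- function(records, positions, r2_lookup, r2_max, window_kb) {
  remaining <- records
  index_ids <- character(0)
  while (nrow(remaining) > 0) {
    best <- remaining[order(remaining$pval, remaining$snp_id)[1], ]
    index_ids <- c(index_ids, best$snp_id)
    keep <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      r <- remaining[i, ]
      if (r$snp_id == best$snp_id) next
      pi <- positions[positions$snp_id == best$snp_id, ]
      pj <- positions[positions$snp_id == r$snp_id, ]
      linked <- pi$chrom == pj$chrom &&
        abs(pi$bp - pj$bp) <= window_kb * 1000 &&
        r2_lookup(best$snp_id, r$snp_id) >= r2_max
      keep[i] <- !linked
    }
    remaining <- remaining[keep, , drop = FALSE]
  }
  sort(index_ids)
}

# Build a harmonized_set directly from effect vectors (bypasses file IO
# and harmonization; used to feed estimators exact configurations).
make_hset <- function(beta_exp, beta_out, se_exp, se_out,
                      eaf_exp = rep(0.3, length(beta_exp)),
                      eaf_out = eaf_exp,
                      n_exp = rep(100000L, length(beta_exp)),
                      n_out = n_exp,
                      snp_id = sprintf("rs%04d", seq_along(beta_exp))) {
  L <- length(beta_exp)
  pairs <- data.frame(
    snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
    eaf_exp = eaf_exp, pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    n_exp = as.integer(n_exp), beta_out = beta_out, se_out = se_out,
    eaf_out = eaf_out, pval_out = 2 * pnorm(-abs(beta_out / se_out)),
    n_out = as.integer(n_out), flipped = rep(FALSE, L),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 exclusion_log = data.frame(snp_id = character(0),
                                            stage = character(0),
                                            reason = character(0),
                                            stringsAsFactors = FALSE),
                 exposure_label = "exp", outcome_label = "out"),
            class = "harmonized_set")
}

# Build a summary_stats object from loose vectors with sensible defaults.
make_ss <- function(snp_id, beta, se, pval, eaf = 0.3, n = 100000L,
                    ea = "A", oa = "G", label = "trait") {
  L <- length(snp_id)
  rec <- data.frame(snp_id = snp_id,
                    effect_allele = rep_len(ea, L),
                    other_allele = rep_len(oa, L),
                    beta = beta, se = se, eaf = rep_len(eaf, L),
                    pval = pval, n = as.integer(rep_len(n, L)),
                    stringsAsFactors = FALSE)
  summary_stats(rec, trait_label = label)
}

# random valid summary_stats for round-trip property tests
random_ss <- function(L, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, L, TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), "")
  eaf <- runif(L, 0.01, 0.99)
  eaf[runif(L) < 0.2] <- NA
  rec <- data.frame(snp_id = sprintf("rs%06d", sample.int(1e6, L)),
                    effect_allele = ea, other_allele = unname(oa),
                    beta = rnorm(L), se = rexp(L) + 1e-4,
                    eaf = eaf, pval = runif(L),
                    n = sample.int(500000L, L) + 100L,
                    stringsAsFactors = FALSE)
  summary_stats(rec, trait_label = "random", provenance = "helper")
}
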