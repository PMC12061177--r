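test_that("exposure p-value filter keeps strictly sub-threshold records", {
  ss <- make_ss(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                pval = c(1e-9, 4e-8, 6e-8))
  expect_equal(filter_by_exposure_p(ss, 5e-8)$records$snp_id,
               c("rs1", "rs2"))
  expect_equal(nsnp(filter_by_exposure_p(ss, 5e-6)), 3)
  empty <- filter_by_exposure_p(ss, 1e-20)
  expect_equal(nsnp(empty), 0)
})

test_that("greedy clumping keeps the best SNP and respects the window", {
  pos <- data.frame(snp_id = c("rs1", "rs2"), chrom = c(1, 1),
                    bp = c(1e6, 1.005e6))
  ld <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5), pos)
  ss <- make_ss(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                pval = c(1e-10, 1e-9))
  expect_equal(ld_clump(ss, ld, r2_max = 0.001)$records$snp_id, "rs1")
  # same r2 but different chromosomes: the window never spans chromosomes
  pos2 <- data.frame(snp_id = c("rs1", "rs2"), chrom = c(1, 2),
                     bp = c(1e6, 1.005e6))
  ld2 <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9), pos2)
  expect_equal(nsnp(ld_clump(ss, ld2, r2_max = 0.001)), 2)
  # SNP absent from the position table is a hard error naming it
  pos3 <- pos[1, , drop = FALSE]
  expect_error(ld_clump(ss, ld_info(data.frame(snp_a = character(0),
                                               snp_b = character(0),
                                               r2 = numeric(0)), pos3)),
               "rs2")
})

test_that("ld_clump matches the brute-force oracle on random instances", {
  for (seed in 1:60) {
    set.seed(seed)
    L <- sample(2:12, 1)
    ids <- sprintf("rs%03d", sample.int(999, L))
    pos <- data.frame(snp_id = ids,
                      chrom = sample(1:2, L, TRUE),
                      bp = sample.int(3e7, L))
    cmb <- if (L > 1) utils::combn(ids, 2) else matrix(character(0), 2, 0)
    pairs <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                        r2 = round(runif(ncol(cmb)), 2),
                        stringsAsFactors = FALSE)
    ld <- ld_info(pairs, pos)
    ss <- make_ss(ids, beta = 0.1, se = 0.01,
                  pval = round(runif(L), 3) + 1e-6)
    r2_max <- sample(c(0.001, 0.3, 0.7), 1)
    window <- sample(c(100, 5000, 10000), 1)
    got <- sort(ld_clump(ss, ld, r2_max, window)$records$snp_id)
    want <- oracle_clump(ss$records, pos, ld$lookup, r2_max, window)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("instrument strength follows the R2/F formulas", {
  s <- instrument_strength(beta = 0.1, eaf = 0.5, n = 10002)
  expect_equal(s$r2, 0.005)
  expect_equal(s$f_stat, 0.005 * 10000 / 0.995, tolerance = 1e-12)
  expect_equal(s$f_stat, 50.25126, tolerance = 1e-6)
  s <- instrument_strength(beta = 0.05, eaf = 0.3, n = 130644)
  expect_equal(s$r2, 2 * 0.3 * 0.7 * 0.0025)
  expect_equal(s$f_stat, 137.3, tolerance = 1e-3)
  expect_equal(instrument_strength(0, 0.5, 1000)$f_stat, 0)
  expect_null(instrument_strength(0.1, NA, 1000))
  # monotone in |beta| and in N for fixed EAF
  f_of <- function(b, n) instrument_strength(b, 0.25, n)$f_stat
  bs <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(vapply(bs, f_of, 0, n = 50000)) > 0))
  ns <- seq(1000, 500000, length.out = 20)
  expect_true(all(diff(vapply(ns, function(n) f_of(0.1, n), 0)) > 0))
})

test_that("strength, outcome-association and confounder filters exclude and log", {
  # f_stat just below 10: eaf 0.5, n 10000 -> r2 needed ~ 0.001
  b_weak <- sqrt(9.9 / (10000 - 2 + 9.9) / (2 * 0.25))
  b_strong <- sqrt(200 / (10000 - 2 + 200) / (2 * 0.25))
  h <- make_hset(beta_exp = c(b_weak, b_strong, b_strong, b_strong),
                 beta_out = c(0.01, 0.01, 0.05, 0.01),
                 se_exp = rep(0.01, 4), se_out = c(0.01, 0.01, 0.01, 0.01),
                 eaf_exp = rep(0.5, 4), n_exp = rep(10000L, 4))
  h$pairs$pval_out <- c(0.5, 0.5, 1e-6, 0.5)
  crit <- mr_criteria(exclusion_list = "rs0004")
  out <- apply_filters(h, crit)
  expect_equal(out$pairs$snp_id, "rs0002")
  log <- out$exclusion_log
  expect_equal(log$reason[log$snp_id == "rs0001"], "weak_instrument")
  expect_equal(log$reason[log$snp_id == "rs0003"], "outcome_associated")
  expect_equal(log$reason[log$snp_id == "rs0004"], "confounder")
  # missing eaf is excluded conservatively, not imputed
  h2 <- make_hset(beta_exp = rep(b_strong, 2), beta_out = c(0.01, 0.01),
                  se_exp = rep(0.01, 2), se_out = rep(0.01, 2),
                  eaf_exp = c(NA, 0.5), n_exp = rep(10000L, 2))
  out2 <- apply_filters(h2, mr_criteria())
  expect_equal(out2$exclusion_log$reason, "no_eaf")
  # idempotence: a second application changes nothing
  out3 <- apply_filters(out2, mr_criteria())
  expect_equal(out3$pairs, out2$pairs)
  expect_equal(nrow(out3$exclusion_log), nrow(out2$exclusion_log))
})

test_that("Steiger filter removes reverse-direction SNPs", {
  # r2 = 2*eaf*(1-eaf)*beta^2 with eaf 0.5: r2 = beta^2/2
  h <- make_hset(beta_exp = c(sqrt(0.02), sqrt(2e-4), 0.1),
                 beta_out = c(sqrt(2e-4), sqrt(0.02), 0.1),
                 se_exp = rep(0.01, 3), se_out = rep(0.01, 3),
                 eaf_exp = rep(0.5, 3), n_exp = rep(50000L, 3))
  st <- steiger_test(h)
  expect_true(st$direction_true[1])   # r2_exp 0.01 >> r2_out 1e-4
  expect_false(st$direction_true[2])  # reversed
  # equal variance explained: z = 0, one-sided p = 0.5, not kept
  expect_equal(st$z[3], 0)
  expect_equal(st$pval[3], 0.5)
  out <- steiger_filter(h)
  expect_equal(out$pairs$snp_id, "rs0001")
  expect_setequal(out$exclusion_log$reason, "steiger_false")
  # z matches the Fisher-z difference formula directly
  z_direct <- (atanh(sqrt(0.01)) - atanh(sqrt(1e-4))) /
    sqrt(2 / (50000 - 3))
  expect_equal(st$z[1], z_direct)
  # untestable SNPs (missing eaf) pass with a warning
  h$pairs$eaf_out[1] <- NA
  expect_warning(kept <- steiger_filter(h), "untestable")
  expect_true("rs0001" %in% kept$pairs$snp_id)
})

test_that("Steiger filter retains nearly all valid strong instruments", {
  sim <- simulate_pair(sim_config(n_snp = 200, theta = 0.1, f_floor = 30,
                                  seed = 404))
  h <- harmonize_set(sim$exposure, sim$outcome)
  kept <- steiger_filter(h)
  expect_gte(nrow(kept$pairs) / nrow(h$pairs), 0.95)
})

test_that("pooled-set Steiger mode reports a single set-level direction", {
  sim <- simulate_pair(sim_config(n_snp = 50, theta = 0.1, f_floor = 30,
                                  seed = 405))
  h <- harmonize_set(sim$exposure, sim$outcome)
  st <- steiger_test(h, mode = "pooled")
  expect_equal(nrow(st), 1)
  expect_true(st$direction_true)
  expect_equal(st$n_snp_used, 50)
})
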