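test_that("Cochran's Q under the IVW and Egger models", {
  h <- make_hset(beta_exp = c(1, 1), beta_out = c(0.5, 0.3),
                 se_exp = c(0.01, 0.01), se_out = c(0.2, 0.1))
  q <- cochran_q(h, "ivw")
  expect_equal(q$Q, 0.8)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(0.8, 1, lower.tail = FALSE))
  # identical ratios: Q = 0, p = 1
  h2 <- make_hset(beta_exp = c(1, 2, 3), beta_out = c(0.4, 0.8, 1.2),
                  se_exp = rep(0.01, 3), se_out = rep(0.1, 3))
  expect_equal(cochran_q(h2, "ivw")$Q, 0, tolerance = 1e-24)
  expect_equal(cochran_q(h2, "ivw")$pval, 1)
  # data on a line with nonzero intercept: Q' = 0 under Egger, Q > 0 under IVW
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h3 <- make_hset(beta_exp = bx, beta_out = 0.03 + 0.2 * bx,
                  se_exp = rep(0.005, 4), se_out = rep(0.01, 4))
  expect_lt(cochran_q(h3, "egger")$Q, 1e-16)
  expect_gt(cochran_q(h3, "ivw")$Q, 1)
  expect_equal(cochran_q(h3, "egger")$df, 2)
  expect_error(cochran_q(make_hset(1, 1, 0.1, 0.1), "ivw"), ">= 2")
})

test_that("Egger intercept test recovers zero and planted pleiotropy", {
  bx <- seq(0.05, 0.4, length.out = 10)
  h <- make_hset(beta_exp = bx, beta_out = 0.3 * bx,
                 se_exp = rep(0.005, 10), se_out = rep(0.01, 10))
  it <- egger_intercept_test(h)
  expect_equal(it$value, 0, tolerance = 1e-12)
  expect_gt(it$pval, 0.99)
  # all-SNP directional pleiotropy alpha = 0.05: mean intercept ~ alpha
  reps <- vapply(1:150, function(i) {
    sim <- simulate_pair(sim_config(n_snp = 30, theta = 0.1, f_floor = 30,
                                    pleiotropy_mode = "directional",
                                    prop_invalid = 1, pleiotropy_mean = 0.05,
                                    pleiotropy_sd = 0.02, seed = 6000 + i))
    egger_intercept_test(harmonize_set(sim$exposure, sim$outcome))$value
  }, 0)
  expect_lt(abs(mean(reps) - 0.05), 3 * sd(reps) / sqrt(150) + 0.003)
})

test_that("MR-PRESSO is seeded-deterministic with bounded global p", {
  sim <- simulate_pair(sim_config(n_snp = 15, theta = 0.1, f_floor = 30,
                                  seed = 21))
  h <- harmonize_set(sim$exposure, sim$outcome)
  a <- mr_presso(h, n_sim = 300, seed = 42)
  b <- mr_presso(h, n_sim = 300, seed = 42)
  expect_identical(a, b)
  expect_gte(a$global_p, 1 / 301)
  expect_lte(a$global_p, 1)
  expect_length(a$outlier_p, 15)
  # concordant data: no outliers, distortion test not applicable
  expect_length(a$outlier_ids, 0)
  expect_true(is.na(a$distortion_p))
  expect_error(mr_presso(make_hset(c(1, 1, 1), c(1, 1, 1), rep(0.1, 3),
                                   rep(0.1, 3)), seed = 1), "4 instruments")
})

test_that("MR-PRESSO flags a planted gross outlier and reports distortion", {
  sim <- simulate_pair(sim_config(n_snp = 20, theta = 0.1, f_floor = 30,
                                  seed = 33))
  h <- harmonize_set(sim$exposure, sim$outcome)
  h$pairs$beta_out[7] <- h$pairs$beta_out[7] + 10 * h$pairs$se_out[7]
  res <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_true(h$pairs$snp_id[7] %in% res$outlier_ids)
  expect_lt(res$global_p, 0.05)
  expect_false(is.na(res$distortion_p))
})

test_that("MR-PRESSO global p is uniform under concordant null data", {
  ps <- vapply(1:200, function(i) {
    sim <- simulate_pair(sim_config(n_snp = 10, theta = 0.1, f_floor = 30,
                                    seed = 9000 + i))
    h <- harmonize_set(sim$exposure, sim$outcome)
    mr_presso(h, n_sim = 200, seed = 9000 + i)$global_p
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))  # ties from the p grid
  expect_gt(ks$p.value, 0.01)
})

test_that("radial q decomposes Cochran's Q exactly under first-order weights", {
  sim <- simulate_pair(sim_config(n_snp = 30, theta = 0.05, f_floor = 30,
                                  seed = 64, pleiotropy_mode = "balanced",
                                  prop_invalid = 0.3, pleiotropy_sd = 0.02))
  h <- harmonize_set(sim$exposure, sim$outcome)
  rad <- radial_mr(h, weights = "first")
  q <- cochran_q(h, "ivw")
  expect_equal(rad$total_q, q$Q, tolerance = 1e-12)
  expect_equal(sum(rad$q$q_j), q$Q, tolerance = 1e-12)
  expect_true(all(rad$q$q_j >= 0))
  expect_equal(rad$beta_radial, ivw(h, "fe")$beta)
  # identical ratios: all contributions vanish, no outliers
  h2 <- make_hset(beta_exp = c(1, 2, 3), beta_out = c(0.4, 0.8, 1.2),
                  se_exp = rep(0.01, 3), se_out = rep(0.1, 3))
  expect_equal(radial_mr(h2)$q$q_j, rep(0, 3), tolerance = 1e-22)
  expect_length(radial_mr(h2)$outlier_ids, 0)
  # planted outlier flagged at alpha = 0.05; second-order weights differ
  h$pairs$beta_out[5] <- h$pairs$beta_out[5] + 10 * h$pairs$se_out[5]
  expect_true(h$pairs$snp_id[5] %in% radial_mr(h, 0.05)$outlier_ids)
  rad2 <- radial_mr(h, weights = "second")
  expect_false(isTRUE(all.equal(rad2$total_q, radial_mr(h)$total_q)))
})

test_that("leave-one-out rows equal independently computed subset IVW", {
  sim <- simulate_pair(sim_config(n_snp = 3, theta = 0.1, f_floor = 30,
                                  seed = 55))
  h <- harmonize_set(sim$exposure, sim$outcome)
  loo <- leave_one_out(h)
  for (j in 1:3) {
    sub <- h
    sub$pairs <- h$pairs[-j, , drop = FALSE]
    ref <- ivw(sub, "mre")
    expect_equal(loo$beta[j], ref$beta)
    expect_equal(loo$se[j], ref$se)
  }
  # identical ratios: every row equals the full estimate
  h2 <- make_hset(beta_exp = c(1, 2, 3, 4), beta_out = 0.3 * c(1, 2, 3, 4),
                  se_exp = rep(0.01, 4), se_out = rep(0.1, 4))
  loo2 <- leave_one_out(h2)
  expect_equal(loo2$beta, rep(0.3, 4), tolerance = 1e-12)
  expect_false(any(loo2$influential))
  # a dominant SNP carrying all the signal is flagged influential
  h3 <- make_hset(beta_exp = c(1, 1, 1, 1),
                  beta_out = c(0.02, -0.01, 0.015, 0.6),
                  se_exp = rep(0.01, 4),
                  se_out = c(0.3, 0.3, 0.3, 0.01))
  loo3 <- leave_one_out(h3)
  expect_true(loo3$influential[4])
})

test_that("the sensitivity report bundles all diagnostics coherently", {
  sim <- simulate_pair(sim_config(n_snp = 12, theta = 0.1, f_floor = 30,
                                  seed = 70))
  h <- harmonize_set(sim$exposure, sim$outcome)
  rep <- sensitivity_report(h, seed = 3, presso_n_sim = 200)
  expect_equal(rep$q_ivw$df, 11)
  expect_equal(rep$q_egger$df, 10)
  expect_equal(nrow(rep$loo), 12)
  expect_equal(rep$radial$total_q, rep$q_ivw$Q, tolerance = 1e-12)
  expect_s3_class(rep, "sensitivity_report")
})
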