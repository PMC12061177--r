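test_that("Wald ratio arithmetic and sign behaviour", {
  h <- make_hset(0.1, 0.05, 0.01, 0.02)
  est <- wald_ratio(h$pairs)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(est$ci_low, 0.5 - 1.96 * 0.2)
  expect_equal(wald_ratio(make_hset(0.1, 0, 0.01, 0.02)$pairs)$beta, 0)
  est2 <- wald_ratio(make_hset(-0.1, 0.05, 0.01, 0.02)$pairs)
  expect_equal(est2$beta, -0.5)
  expect_equal(est2$se, 0.2)
  expect_error(wald_ratio(make_hset(0, 0.05, 0.01, 0.02)$pairs),
               "undefined")
})

test_that("IVW matches the closed form and its degenerate cases", {
  # ratios 0.5 (se 0.2) and 0.3 (se 0.1): use unit exposure effects
  h <- make_hset(beta_exp = c(1, 1), beta_out = c(0.5, 0.3),
                 se_exp = c(0.01, 0.01), se_out = c(0.2, 0.1))
  fe <- ivw(h, mode = "fe")
  expect_equal(fe$beta, (0.5 * 25 + 0.3 * 100) / 125)
  expect_equal(fe$beta, 0.34)
  expect_equal(fe$se, sqrt(1 / 125))
  expect_equal(fe$extra$Q, 25 * (0.5 - 0.34)^2 + 100 * (0.3 - 0.34)^2)
  # identical ratios: Q = 0 and the random-effects floor keeps se_fe
  h2 <- make_hset(beta_exp = c(1, 2, 4), beta_out = c(0.4, 0.8, 1.6),
                  se_exp = rep(0.01, 3), se_out = c(0.1, 0.2, 0.1))
  expect_equal(ivw(h2, "mre")$beta, 0.4)
  expect_equal(ivw(h2, "mre")$extra$Q, 0, tolerance = 1e-20)
  expect_equal(ivw(h2, "mre")$se, ivw(h2, "fe")$se)
  # a single pair reduces to the Wald ratio
  h1 <- make_hset(0.1, 0.05, 0.01, 0.02)
  expect_equal(ivw(h1)$beta, wald_ratio(h1$pairs)$beta)
  expect_equal(ivw(h1)$se, wald_ratio(h1$pairs)$se)
  expect_equal(ivw(h1)$extra$fallback, "wald_ratio")
})

test_that("MR-Egger recovers exact linear structure", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_hset(beta_exp = bx, beta_out = 0.02 + 0.4 * bx,
                 se_exp = rep(0.005, 5), se_out = rep(0.01, 5))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$extra$intercept, 0.02, tolerance = 1e-10)
  expect_equal(est$extra$Q_egger, 0, tolerance = 1e-16)
  # proportional through the origin: zero intercept, slope = common ratio
  h2 <- make_hset(beta_exp = bx, beta_out = 0.25 * bx,
                  se_exp = rep(0.005, 5), se_out = rep(0.01, 5))
  est2 <- mr_egger(h2)
  expect_equal(est2$extra$intercept, 0, tolerance = 1e-12)
  expect_equal(est2$beta, 0.25, tolerance = 1e-10)
  expect_error(mr_egger(make_hset(c(1, 1), c(1, 1), c(0.1, 0.1),
                                  c(0.1, 0.1))), "3 instruments")
  # exact-fit 3-SNP data: residual inflation floored at 1 keeps finite se
  h3 <- make_hset(beta_exp = bx[1:3], beta_out = 0.01 + 0.3 * bx[1:3],
                  se_exp = rep(0.005, 3), se_out = rep(0.01, 3))
  est3 <- mr_egger(h3)
  expect_true(is.finite(est3$se) && est3$se > 0)
})

test_that("weighted median interpolates the weighted 50th percentile", {
  h <- make_hset(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.5, 0.9),
                 se_exp = rep(0.01, 3), se_out = rep(0.1, 3))
  est <- weighted_median(h, n_boot = 200, seed = 5)
  expect_equal(est$beta, 0.5)
  # weight concentrated on one SNP pulls the median to its ratio
  h2 <- make_hset(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.5, 0.9),
                  se_exp = rep(0.01, 3), se_out = c(0.5, 0.5, 0.02))
  expect_equal(weighted_median(h2, n_boot = 200, seed = 5)$beta, 0.9,
               tolerance = 0.05)
  # same seed, same answer; seed is mandatory
  a <- weighted_median(h, n_boot = 200, seed = 9)
  b <- weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_error(weighted_median(h, n_boot = 10), "seed")
})

test_that("cML-MA handles clean data, a planted outlier, and the K=0 limit", {
  bx <- seq(0.05, 0.3, length.out = 8)
  # near-exact data: K = 0 takes essentially all BIC weight
  h <- make_hset(beta_exp = bx, beta_out = 0.12 * bx,
                 se_exp = rep(1e-4, 8), se_out = rep(1e-4, 8))
  est <- cml_ma(h)
  expect_equal(est$beta, 0.12, tolerance = 1e-6)
  # K = 0 is the BIC-best model and carries the largest weight (for exact
  # data all deviances vanish, so weights decay geometrically in K)
  expect_equal(est$extra$best_k, 0)
  expect_equal(which.max(est$extra$bic_weights), c(K0 = 1L))
  # one grossly pleiotropic SNP: K = 1 dominates and its support is exact
  by <- 0.12 * bx; by[4] <- by[4] + 0.05
  h2 <- make_hset(beta_exp = bx, beta_out = by,
                  se_exp = rep(1e-3, 8), se_out = rep(1e-3, 8))
  est2 <- cml_ma(h2)
  expect_equal(est2$extra$best_k, 1)
  expect_equal(est2$extra$best_k_support, "rs0004")
  expect_equal(est2$beta, 0.12, tolerance = 1e-3)
  # K = 0 with negligible exposure noise matches fixed-effect IVW
  sim <- simulate_pair(sim_config(n_snp = 20, theta = 0.1, f_floor = 30,
                                  seed = 99))
  h3 <- harmonize_set(sim$exposure, sim$outcome)
  h3$pairs$se_exp <- rep(1e-6, 20)
  expect_equal(cml_ma(h3, k_grid = 0)$beta, ivw(h3, "fe")$beta,
               tolerance = 1e-4)
  expect_error(cml_ma(h, k_grid = c(0, 7)), "k_grid")
})

test_that("estimators are order-invariant and sign-equivariant", {
  sim <- simulate_pair(sim_config(n_snp = 25, theta = 0.1, f_floor = 30,
                                  seed = 12))
  h <- harmonize_set(sim$exposure, sim$outcome)
  perm <- sample(nrow(h$pairs))
  hp <- h; hp$pairs <- h$pairs[perm, ]
  for (fn in list(function(x) ivw(x)$beta,
                  function(x) mr_egger(x)$beta,
                  function(x) cml_ma(x)$beta)) {
    expect_equal(fn(h), fn(hp), tolerance = 1e-9)
  }
  # weighted median point estimate is order-invariant (bootstrap aside)
  expect_equal(weighted_median(h, 50, seed = 1)$beta,
               weighted_median(hp, 50, seed = 1)$beta)
  # negating both sides leaves beta unchanged; negating the outcome flips it
  neg_both <- h; neg_both$pairs$beta_exp <- -h$pairs$beta_exp
  neg_both$pairs$beta_out <- -h$pairs$beta_out
  neg_out <- h; neg_out$pairs$beta_out <- -h$pairs$beta_out
  for (fn in list(function(x) ivw(x)$beta,
                  function(x) mr_egger(x)$beta,
                  function(x) weighted_median(x, 50, seed = 3)$beta,
                  function(x) cml_ma(x)$beta)) {
    expect_equal(fn(neg_both), fn(h), tolerance = 1e-8)
    expect_equal(fn(neg_out), -fn(h), tolerance = 1e-8)
  }
})
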