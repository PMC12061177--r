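#' Cochran's Q heterogeneity test
#'
#' Under the IVW model, Q = sum_j w_j (ratio_j - beta_ivw_fe)^2 with
#' first-order inverse-variance weights, referred to chi-square with
#' L - 1 degrees of freedom. Under the Egger model, Rucker's Q' is the
#' weighted residual sum of squares about the MR-Egger fit on L - 2
#' degrees of freedom.
#'
#' @param hset a `harmonized_set`.
#' @param model `"ivw"` (needs >= 2 instruments) or `"egger"` (>= 3).
#' @return A list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(hset, model = c("ivw", "egger")) {
  stopifnot(inherits(hset, "harmonized_set"))
  model <- match.arg(model)
  L <- nrow(hset$pairs)
  if (model == "ivw") {
    if (L < 2) stop("cochran_q (ivw) needs >= 2 instruments", call. = FALSE)
    est <- ivw(hset, mode = "fe")
    Q <- est$extra$Q
    df <- L - 1
  } else {
    if (L < 3) stop("cochran_q (egger) needs >= 3 instruments",
                    call. = FALSE)
    Q <- mr_egger(hset)$extra$Q_egger
    df <- L - 2
  }
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept row of the [mr_egger] fit with a two-sided normal
#' p-value; a nonzero intercept indicates directional pleiotropy.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @return A list with `value`, `se`, `pval`.
#' @export
egger_intercept_test <- function(hset) {
  e <- mr_egger(hset)$extra
  list(value = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

# IVW slope as weighted regression through the origin of beta_out on
# beta_exp with weights 1/se_out^2 (identical to the Wald-ratio IVW)
ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' The observed statistic is RSS_obs = sum_j w_j (beta_out_j -
#' theta_hat_(-j) * beta_exp_j)^2 with w_j = 1/se_out_j^2 and
#' theta_hat_(-j) the leave-one-out IVW slope. The null distribution is
#' simulated: each replicate draws beta_exp*_j ~ Normal(beta_exp_j,
#' se_exp_j) and beta_out*_j ~ Normal(theta_hat_(-j) * beta_exp_j,
#' se_out_j) and recomputes RSS with its own leave-one-out slopes. The
#' global p-value is (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1); per-SNP
#' outlier p-values are the empirical tails of each observed residual
#' against its simulated distribution, Bonferroni-corrected by L, with
#' outliers called below `sig`. When outliers exist, the distortion test
#' compares the outlier-free IVW slope against slopes after removing
#' equally many random SNPs.
#'
#' @param hset a `harmonized_set` with at least 4 instruments.
#' @param n_sim number of simulated replicates.
#' @param seed integer seed (results are bit-reproducible given the seed).
#' @param sig significance level for outlier calls (applied to the
#'   Bonferroni-corrected per-SNP p).
#' @return A list with `global_p`, `rss_obs`, `outlier_ids`, `outlier_p`
#'   (per SNP, corrected), `distortion_p` (NA when no outliers), `n_sim`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed, sig = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (missing(seed)) stop("mr_presso requires a seed", call. = FALSE)
  p <- hset$pairs
  L <- nrow(p)
  if (L < 4) stop("mr_presso needs at least 4 instruments", call. = FALSE)
  bx <- p$beta_exp; by <- p$beta_out
  w <- 1 / p$se_out^2

  loo_slopes <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  th_loo <- loo_slopes(bx, by)
  res2_obs <- w * (by - th_loo * bx)^2
  rss_obs <- sum(res2_obs)

  sims <- with_seed(seed, {
    res2_sim <- matrix(0, n_sim, L)
    for (s in seq_len(n_sim)) {
      bxs <- stats::rnorm(L, bx, p$se_exp)
      bys <- stats::rnorm(L, th_loo * bx, p$se_out)
      r2 <- w * (bys - loo_slopes(bxs, bys) * bxs)^2
      res2_sim[s, ] <- r2
    }
    res2_sim
  })
  rss_sim <- rowSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + colSums(sims >= matrix(res2_obs, n_sim, L, byrow = TRUE))) /
    (n_sim + 1)
  corr_p <- pmin(1, raw_p * L)
  outliers <- p$snp_id[corr_p < sig]

  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < L - 1) {
    keep <- !(p$snp_id %in% outliers)
    th_full <- ivw_slope(bx, by, w)
    th_no_out <- ivw_slope(bx[keep], by[keep], w[keep])
    d_obs <- th_no_out - th_full
    k <- length(outliers)
    d_rand <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop <- sample.int(L, k)
        ivw_slope(bx[-drop], by[-drop], w[-drop]) - th_full
      }, 0)
    })
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_p = global_p, rss_obs = rss_obs, outlier_ids = outliers,
       outlier_p = stats::setNames(corr_p, p$snp_id),
       distortion_p = distortion_p, n_sim = n_sim, sig = sig)
}

#' Radial MR outlier diagnostics
#'
#' The radial reformulation of IVW exposes each SNP's contribution to
#' Cochran's Q: q_j = w_j (ratio_j - beta_radial)^2 where beta_radial is
#' the radial (weighted through-origin) IVW slope. With first-order
#' weights (the default) the q_j sum exactly to the IVW Cochran Q.
#' Modified second-order weights additionally propagate the exposure-side
#' uncertainty. Each q_j is referred to chi-square with one degree of
#' freedom; SNPs with p_j below `alpha` are flagged as outliers.
#'
#' @param hset a `harmonized_set` with at least 2 instruments.
#' @param alpha per-SNP outlier significance threshold.
#' @param weights `"first"` (first-order, default) or `"second"`
#'   (modified second-order).
#' @return A list with `beta_radial`, per-SNP table `q` (snp_id, q_j,
#'   p_j), `outlier_ids` and `total_q`.
#' @export
radial_mr <- function(hset, alpha = 0.05, weights = c("first", "second")) {
  stopifnot(inherits(hset, "harmonized_set"))
  weights <- match.arg(weights)
  p <- hset$pairs
  L <- nrow(p)
  if (L < 2) stop("radial_mr needs at least 2 instruments", call. = FALSE)
  wc <- wald_components(p)
  w <- if (weights == "first") {
    1 / wc$se^2
  } else {
    1 / (p$se_out^2 / p$beta_exp^2 +
           p$beta_out^2 * p$se_exp^2 / p$beta_exp^4)
  }
  beta_radial <- sum(w * wc$ratio) / sum(w)
  q_j <- w * (wc$ratio - beta_radial)^2
  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
  tab <- data.frame(snp_id = p$snp_id, q_j = q_j, p_j = p_j,
                    stringsAsFactors = FALSE)
  list(beta_radial = beta_radial, q = tab,
       outlier_ids = p$snp_id[p_j < alpha], total_q = sum(q_j),
       weights = weights)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect L times, omitting one SNP at a time,
#' and flags influential SNPs whose omission flips the sign of the
#' estimate or moves its p-value across 0.05.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param ivw_mode forwarded to [ivw].
#' @return A data.frame with one row per left-out SNP (`snp_id`, `beta`,
#'   `se`, `pval`, `influential`) plus the full-set estimate in attribute
#'   `"full"`.
#' @export
leave_one_out <- function(hset, ivw_mode = "mre") {
  stopifnot(inherits(hset, "harmonized_set"))
  L <- nrow(hset$pairs)
  if (L < 3) stop("leave_one_out needs at least 3 instruments",
                  call. = FALSE)
  full <- ivw(hset, mode = ivw_mode)
  rows <- lapply(seq_len(L), function(j) {
    sub <- hset
    sub$pairs <- hset$pairs[-j, , drop = FALSE]
    est <- ivw(sub, mode = ivw_mode)
    data.frame(snp_id = hset$pairs$snp_id[j], beta = est$beta, se = est$se,
               pval = est$pval,
               influential = sign(est$beta) != sign(full$beta) ||
                 (est$pval < 0.05) != (full$pval < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Full sensitivity battery for one harmonized set
#'
#' Runs Cochran's Q under both the IVW and Egger models, the Egger
#' intercept test, MR-PRESSO, radial MR and leave-one-out, collecting the
#' pieces into one report.
#'
#' @param hset a `harmonized_set`.
#' @param seed integer seed for MR-PRESSO.
#' @param presso_n_sim MR-PRESSO replicate count.
#' @param radial_alpha radial outlier threshold.
#' @param presso_sig MR-PRESSO outlier significance.
#' @return A list of class `sensitivity_report` with elements `q_ivw`,
#'   `q_egger`, `egger_intercept`, `presso`, `radial`, `loo` (components
#'   needing more instruments than available are `NULL`).
#' @export
sensitivity_report <- function(hset, seed, presso_n_sim = 1000,
                               radial_alpha = 0.05, presso_sig = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  L <- nrow(hset$pairs)
  maybe <- function(expr) tryCatch(expr, error = function(e) NULL)
  structure(list(
    n_snp = L,
    q_ivw = maybe(cochran_q(hset, "ivw")),
    q_egger = maybe(cochran_q(hset, "egger")),
    egger_intercept = maybe(egger_intercept_test(hset)),
    presso = maybe(mr_presso(hset, n_sim = presso_n_sim, seed = seed,
                             sig = presso_sig)),
    radial = maybe(radial_mr(hset, alpha = radial_alpha)),
    loo = maybe(leave_one_out(hset))
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(
    "<sensitivity_report> %d SNPs | Q(IVW) p=%s, Q(Egger) p=%s, intercept p=%s, PRESSO global p=%s\n",
    x$n_snp, fmt(x$q_ivw$pval), fmt(x$q_egger$pval),
    fmt(x$egger_intercept$pval), fmt(x$presso$global_p)))
  invisible(x)
}
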