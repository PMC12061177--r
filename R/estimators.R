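#' Construct an MR causal-effect estimate
#'
#' @param method one of `wald`, `ivw_fe`, `ivw_mre`, `egger`, `wmedian`,
#'   `cml_ma`.
#' @param beta causal log-odds-ratio per unit of the exposure effect.
#' @param se standard error of `beta`.
#' @param n_snp number of instruments used.
#' @param extra method-specific named list (e.g. Egger intercept, cML-MA
#'   BIC weights).
#' @return An object of class `mr_estimate` with normal-theory 95% CI and
#'   two-sided normal p-value.
#' @keywords internal
mr_estimate <- function(method, beta, se, n_snp, extra = list()) {
  ci <- ci_bounds(beta, se)
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = ci[1], ci_high = ci[2],
         pval = norm_pval(beta, se), n_snp = n_snp, extra = extra),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- effect_to_or(x$beta, x$se)
  cat(sprintf(
    "<mr_estimate> %s (%d SNPs): beta=%.4g (se %.4g), OR=%.3f [%.3f, %.3f], p=%.3g\n",
    x$method, x$n_snp, x$beta, x$se, or$or, or$ci_low, or$ci_high, x$pval))
  invisible(x)
}

# per-pair Wald ratio and first-order delta-method se, vectorized
wald_components <- function(pairs) {
  if (any(pairs$beta_exp == 0)) {
    stop("Wald ratio undefined: zero exposure effect for SNP(s) ",
         paste(pairs$snp_id[pairs$beta_exp == 0], collapse = ", "),
         call. = FALSE)
  }
  list(ratio = pairs$beta_out / pairs$beta_exp,
       se = pairs$se_out / abs(pairs$beta_exp))
}

#' Wald ratio estimate from a single harmonized pair
#'
#' beta = beta_out / beta_exp with first-order delta-method standard error
#' se_out / |beta_exp|.
#'
#' @param pair one-row harmonized pair data.frame.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(pair) {
  pair <- as.data.frame(pair)
  stopifnot(nrow(pair) == 1)
  w <- wald_components(pair)
  mr_estimate("wald", w$ratio, w$se, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Meta-analytic combination of per-SNP Wald ratios with weights
#' 1/se_j^2 (se_j the first-order Wald standard error). The fixed-effect
#' standard error is (sum w_j)^(-1/2); the multiplicative-random-effects
#' model (the default) inflates it by max(1, sqrt(Q/(L-1))) where Q is
#' Cochran's Q about the fixed-effect estimate. A single instrument falls
#' back to the Wald ratio, flagged in `extra$fallback`.
#'
#' @param hset a `harmonized_set`.
#' @param mode `"mre"` (multiplicative random effects, default) or `"fe"`
#'   (fixed effect).
#' @return An `mr_estimate` (`ivw_mre` or `ivw_fe`); `extra` carries
#'   Cochran's `Q`.
#' @export
ivw <- function(hset, mode = c("mre", "fe")) {
  stopifnot(inherits(hset, "harmonized_set"))
  mode <- match.arg(mode)
  L <- nrow(hset$pairs)
  if (L < 1) stop("ivw: no instruments", call. = FALSE)
  if (L == 1) {
    est <- wald_ratio(hset$pairs)
    est$method <- paste0("ivw_", mode)
    est$extra <- list(fallback = "wald_ratio", Q = 0)
    return(est)
  }
  wc <- wald_components(hset$pairs)
  w <- 1 / wc$se^2
  beta <- sum(w * wc$ratio) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  Q <- sum(w * (wc$ratio - beta)^2)
  se <- if (mode == "mre") se_fe * max(1, sqrt(Q / (L - 1))) else se_fe
  mr_estimate(paste0("ivw_", mode), beta, se, L, extra = list(Q = Q))
}

# weighted least squares of y on x with intercept; returns coef, se
# (residual-variance scaled with inflation floored at 1), sigma and RSS_w
egger_wls <- function(x, y, w) {
  L <- length(x)
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  coef <- solve(XtWX, XtWy)
  fitted <- X %*% coef
  rss_w <- sum(w * (y - fitted)^2)
  sigma2 <- rss_w / (L - 2)
  unscaled <- sqrt(diag(solve(XtWX)))
  infl <- max(1, sqrt(sigma2))
  list(intercept = coef[1], slope = coef[2],
       se_intercept = unscaled[1] * infl, se_slope = unscaled[2] * infl,
       rss_w = rss_w, sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights 1/se_out^2, after orienting every pair so
#' that beta_exp >= 0 (sign flips applied to both sides; the intercept is
#' orientation-dependent, so a fixed convention keeps results
#' deterministic). The slope estimates the causal effect; a nonzero
#' intercept indicates directional pleiotropy. Both standard errors are
#' inflated by max(1, sqrt(RSS_w/(L-2))).
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @return An `mr_estimate` with method `"egger"`; `extra` holds
#'   `intercept`, `intercept_se`, `intercept_pval` and `Q_egger` (Rucker's
#'   Q': the weighted residual sum of squares about the Egger fit).
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs
  L <- nrow(p)
  if (L < 3) stop("mr_egger needs at least 3 instruments", call. = FALSE)
  s <- ifelse(p$beta_exp < 0, -1, 1)
  x <- s * p$beta_exp
  y <- s * p$beta_out
  w <- 1 / p$se_out^2
  fit <- egger_wls(x, y, w)
  mr_estimate("egger", fit$slope, fit$se_slope, L,
              extra = list(intercept = fit$intercept,
                           intercept_se = fit$se_intercept,
                           intercept_pval = norm_pval(fit$intercept,
                                                      fit$se_intercept),
                           Q_egger = fit$rss_w))
}

# weighted 50th percentile of b with weights w, linear interpolation
# between the straddling order statistics
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(b[1])
  if (cs[length(cs)] <= 0.5) return(b[length(b)])
  k <- max(which(cs < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - cs[k]) / (cs[k + 1] - cs[k])
}

#' Weighted median estimate
#'
#' The weighted 50th percentile of the ordered per-SNP Wald ratios with
#' inverse-variance weights, consistent when instruments carrying at least
#' half the weight are valid. The standard error comes from a seeded
#' parametric bootstrap: each resample draws ratio_j ~ Normal(ratio_j,
#' se_j) and recomputes the weighted median with the original weights.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return An `mr_estimate` with method `"wmedian"`.
#' @export
weighted_median <- function(hset, n_boot = 1000, seed) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (missing(seed)) stop("weighted_median requires a seed", call. = FALSE)
  p <- hset$pairs
  L <- nrow(p)
  if (L < 3) stop("weighted_median needs at least 3 instruments",
                  call. = FALSE)
  wc <- wald_components(p)
  w <- 1 / wc$se^2
  beta <- weighted_median_point(wc$ratio, w)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * L, mean = wc$ratio, sd = wc$se),
                    nrow = L)
    apply(draws, 2, weighted_median_point, w = w)
  })
  mr_estimate("wmedian", beta, stats::sd(boots), L,
              extra = list(n_boot = n_boot, seed = seed))
}

# profile objective for cML given a valid-SNP subset: each valid SNP
# contributes (beta_out - theta*beta_exp)^2 / (se_out^2 + theta^2 se_exp^2)
cml_profile_obj <- function(theta, bx, by, sx2, sy2) {
  sum((by - theta * bx)^2 / (sy2 + theta^2 * sx2))
}

# constrained-ML fit for a fixed number K of invalid instruments
cml_fit_k <- function(K, bx, by, sx2, sy2, theta0, max_iter, tol) {
  L <- length(bx)
  theta <- theta0
  support <- integer(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # residual contribution of each SNP under the profiled (b_j, r_j = 0)
    t_j <- (by - theta * bx)^2 / (sy2 + theta^2 * sx2)
    new_support <- if (K > 0) sort(order(t_j, decreasing = TRUE)[seq_len(K)])
                   else integer(0)
    valid <- setdiff(seq_len(L), new_support)
    # coordinate updates on the valid set: profile b_j, update theta
    th <- theta
    for (inner in seq_len(max_iter)) {
      b <- (bx[valid] / sx2[valid] + th * by[valid] / sy2[valid]) /
        (1 / sx2[valid] + th^2 / sy2[valid])
      th_new <- sum(b * by[valid] / sy2[valid]) / sum(b^2 / sy2[valid])
      if (!is.finite(th_new)) return(NULL)
      if (abs(th_new - th) < tol) { th <- th_new; break }
      th <- th_new
    }
    if (identical(new_support, support) && abs(th - theta) < tol) {
      theta <- th
      support <- new_support
      converged <- TRUE
      break
    }
    support <- new_support
    theta <- th
  }
  if (!converged) return(NULL)
  valid <- setdiff(seq_len(L), support)
  obj <- cml_profile_obj(theta, bx[valid], by[valid], sx2[valid], sy2[valid])
  # curvature of the half-deviance profile -> asymptotic variance
  h <- max(1e-6, 1e-4 * max(abs(theta), 1))
  f0 <- obj
  fp <- cml_profile_obj(theta + h, bx[valid], by[valid], sx2[valid],
                        sy2[valid])
  fm <- cml_profile_obj(theta - h, bx[valid], by[valid], sx2[valid],
                        sy2[valid])
  d2 <- (fp - 2 * f0 + fm) / h^2
  se <- if (d2 > 0) sqrt(2 / d2) else NA_real_
  list(K = K, theta = theta, se = se, objective = obj, support = support)
}

#' Constrained-maximum-likelihood model averaging (cML-MA)
#'
#' For each candidate number K of invalid instruments, minimizes the
#' constrained-ML objective
#' sum_j [ (beta_out_j - theta*b_j - r_j)^2/se_out_j^2 +
#'         (beta_exp_j - b_j)^2/se_exp_j^2 ]
#' with at most K nonzero direct effects r_j, by coordinate iteration:
#' given theta, the K SNPs with the largest profiled squared standardized
#' residuals receive free r_j (their contribution vanishes); given the
#' support, b_j is profiled and theta updated in closed form. Model fit is
#' scored by BIC(K) = deviance(K) + K*log(L) on the profile deviance and
#' the per-K estimates are averaged with weights proportional to
#' exp(-BIC/2). The model-averaged variance combines per-K variances and
#' between-model dispersion.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param k_grid candidate invalid-instrument counts, a subset of
#'   0..(L-2); defaults to the full range.
#' @param max_iter maximum coordinate iterations per K.
#' @param tol convergence threshold on |delta theta|.
#' @param seed kept for interface symmetry with the other estimators; the
#'   fit itself is deterministic.
#' @return An `mr_estimate` with method `"cml_ma"`; `extra` holds the BIC
#'   weights (`bic_weights`), per-K estimates (`per_k`) and the support of
#'   the BIC-best K (`best_k_support`, SNP ids).
#' @export
cml_ma <- function(hset, k_grid = NULL, max_iter = 200, tol = 1e-8,
                   seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs
  L <- nrow(p)
  if (L < 3) stop("cml_ma needs at least 3 instruments", call. = FALSE)
  if (is.null(k_grid)) k_grid <- 0:(L - 2)
  if (any(k_grid < 0 | k_grid > L - 2)) {
    stop("k_grid must be a subset of 0..(n_snp - 2)", call. = FALSE)
  }
  bx <- p$beta_exp; by <- p$beta_out
  sx2 <- p$se_exp^2; sy2 <- p$se_out^2
  theta0 <- ivw(hset, mode = "fe")$beta
  fits <- list()
  for (K in sort(unique(k_grid))) {
    f <- cml_fit_k(K, bx, by, sx2, sy2, theta0, max_iter, tol)
    if (is.null(f) || !is.finite(f$theta) || !is.finite(f$se)) {
      warning("cml_ma: K = ", K, " did not converge; dropped",
              call. = FALSE)
      next
    }
    fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0) {
    stop("cml_ma: no candidate model converged", call. = FALSE)
  }
  bic <- vapply(fits, function(f) f$objective + f$K * log(L), 0)
  wts <- exp(-(bic - min(bic)) / 2)
  wts <- wts / sum(wts)
  thetas <- vapply(fits, `[[`, 0, "theta")
  ses <- vapply(fits, `[[`, 0, "se")
  beta <- sum(wts * thetas)
  se <- sqrt(sum(wts * (ses^2 + (thetas - beta)^2)))
  ks <- vapply(fits, `[[`, 0, "K")
  best <- fits[[which.min(bic)]]
  mr_estimate("cml_ma", beta, se, L,
              extra = list(
                bic_weights = stats::setNames(wts, paste0("K", ks)),
                per_k = data.frame(K = ks, theta = thetas, se = ses,
                                   bic = bic),
                best_k = best$K,
                best_k_support = p$snp_id[best$support]))
}

#' Run a set of MR estimators on one harmonized set
#'
#' @param hset a `harmonized_set`.
#' @param methods subset of `c("ivw", "egger", "wmedian", "cml_ma")`.
#' @param seed integer seed for the weighted-median bootstrap.
#' @param n_boot bootstrap resamples for the weighted median.
#' @param ivw_mode forwarded to [ivw].
#' @return A named list of `mr_estimate` objects (methods needing more
#'   instruments than available are skipped with a warning).
#' @export
mr_estimates <- function(hset, methods = c("ivw", "egger", "wmedian",
                                           "cml_ma"),
                         seed, n_boot = 1000, ivw_mode = "mre") {
  methods <- match.arg(methods, several.ok = TRUE)
  L <- nrow(hset$pairs)
  out <- list()
  for (m in methods) {
    est <- tryCatch(switch(m,
      ivw = ivw(hset, mode = ivw_mode),
      egger = mr_egger(hset),
      wmedian = weighted_median(hset, n_boot = n_boot, seed = seed),
      cml_ma = cml_ma(hset, seed = seed)
    ), error = function(e) {
      warning(m, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(est)) out[[m]] <- est
  }
  out
}
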