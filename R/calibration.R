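#' Repeated-simulation calibration of the MR estimators
#'
#' Runs `n_rep` seeded replicates of the synthetic generator, harmonizes
#' each pair, applies every requested estimator and records its estimate,
#' standard error, p-value and whether the 95% CI covered the true causal
#' effect. This is the engine behind the parameter-recovery, CI-coverage,
#' type-I-error and pleiotropy-robustness checks.
#'
#' @param n_rep number of replicates.
#' @param cfg a [sim_config]; replicate i re-seeds it with
#'   `cfg$seed + i`.
#' @param methods estimators to run (subset of `ivw`, `egger`, `wmedian`,
#'   `cml_ma`).
#' @param n_boot weighted-median bootstrap resamples per replicate.
#' @param ivw_mode forwarded to [ivw].
#' @return A data.frame with one row per (replicate, method): `rep`,
#'   `method`, `beta`, `se`, `pval`, `covered`, plus the Egger intercept
#'   estimate in `intercept` (NA for other methods).
#' @export
calibrate_estimators <- function(n_rep, cfg,
                                 methods = c("ivw", "egger", "wmedian",
                                             "cml_ma"),
                                 n_boot = 500, ivw_mode = "mre") {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- vector("list", n_rep * length(methods))
  k <- 0L
  for (i in seq_len(n_rep)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_pair(cfg_i)
    hset <- harmonize_set(sim$exposure, sim$outcome)
    ests <- mr_estimates(hset, methods = methods, seed = cfg_i$seed,
                         n_boot = n_boot, ivw_mode = ivw_mode)
    for (m in names(ests)) {
      e <- ests[[m]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = i, method = m, beta = e$beta, se = e$se, pval = e$pval,
        covered = e$ci_low <= cfg$theta & cfg$theta <= e$ci_high,
        intercept = if (m == "egger") e$extra$intercept else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Summarize a calibration run
#'
#' @param calib output of [calibrate_estimators].
#' @param theta_true the generating causal effect.
#' @param alpha nominal test level for the rejection rate.
#' @return A data.frame per method with `mean_bias`, `coverage`,
#'   `rejection_rate` (share of replicates with p < `alpha`) and `n_rep`.
#' @export
summarize_calibration <- function(calib, theta_true, alpha = 0.05) {
  out <- lapply(split(calib, calib$method), function(d) {
    data.frame(method = d$method[1],
               mean_bias = mean(d$beta) - theta_true,
               coverage = mean(d$covered),
               rejection_rate = mean(d$pval < alpha),
               mean_intercept = mean(d$intercept),
               n_rep = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detection rate of a planted gross outlier
#'
#' Each replicate simulates a clean study, displaces one SNP's outcome
#' effect by `displace_se` outcome standard errors (a gross pleiotropic
#' outlier), and asks whether MR-PRESSO and radial MR flag exactly that
#' SNP.
#'
#' @param n_rep number of replicates.
#' @param cfg a clean [sim_config] (no pleiotropy).
#' @param displace_se displacement of the planted outlier, in units of its
#'   outcome standard error.
#' @param presso_n_sim MR-PRESSO replicates per run.
#' @param radial_alpha radial outlier threshold.
#' @return A data.frame with per-replicate logicals `presso_hit`,
#'   `radial_hit` (planted SNP among the flagged outliers).
#' @export
planted_outlier_detection <- function(n_rep, cfg, displace_se = 10,
                                      presso_n_sim = 1000,
                                      radial_alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_pair(cfg_i)
    hset <- harmonize_set(sim$exposure, sim$outcome)
    j <- 1L + (i %% nrow(hset$pairs))
    hset$pairs$beta_out[j] <- hset$pairs$beta_out[j] +
      displace_se * hset$pairs$se_out[j]
    planted <- hset$pairs$snp_id[j]
    pres <- mr_presso(hset, n_sim = presso_n_sim, seed = cfg_i$seed)
    rad <- radial_mr(hset, alpha = radial_alpha)
    rows[[i]] <- data.frame(rep = i, planted = planted,
                            presso_hit = planted %in% pres$outlier_ids,
                            radial_hit = planted %in% rad$outlier_ids,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
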