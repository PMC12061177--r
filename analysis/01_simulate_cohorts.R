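#!/usr/bin/env Rscript

# Build the synthetic bidirectional study: one schizophrenia-scale focal
# exposure GWAS analysed against five dementia-scale partner GWAS, each
# pair generated with a known causal effect. Effects are chosen to emulate
# the qualitative pattern of the real analysis: positive causal effects on
# the all-cause-dementia-, Alzheimer- and vascular-dementia-scale cohorts,
# null effects for the two small cohorts. Files are written as plain
# summary-statistic tables so the downstream drivers exercise the full
# text-file interface.

library(mrkit)

out_dir <- "results/simdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

partners <- list(acd = 0.06, ad = 0.03, vad = 0.10, ftd = 0, dlb = 0)
n_focal <- preset("schizophrenia")$n_exp

for (name in names(partners)) {
  cfg <- preset(name, n_snp = 60, theta = partners[[name]], f_floor = 50,
                palindromic_frac = 0.15, strand_flip_frac = 0.2,
                swap_frac = 0.2, seed = 20250500 + match(name, names(partners)))
  cfg$n_out <- cfg$n_exp   # partner cohort size from the preset
  cfg$n_exp <- n_focal     # focal exposure at schizophrenia scale
  sim <- simulate_pair(cfg)
  sim$exposure$trait_label <- "focal"
  sim$outcome$trait_label <- name
  write_sumstats(sim$exposure, file.path(out_dir,
                                         sprintf("focal_for_%s.tsv", name)))
  write_sumstats(sim$outcome, file.path(out_dir, sprintf("%s.tsv", name)))
  write_table(sim$truth$snps, file.path(out_dir,
                                        sprintf("truth_%s.tsv", name)))
  cat(sprintf("%s: theta_true = %.2f, %d SNPs, n_out = %d\n",
              name, partners[[name]], cfg$n_snp, cfg$n_out))

  # reverse pair: the partner trait as exposure through its own
  # instruments (larger per-variant effects, as in small-cohort GWAS
  # hits), null causal effect on the focal trait — the published pattern
  rcfg <- preset(name, n_snp = 40, theta = 0, f_floor = 30,
                 beta_exp_sd = 0.1, palindromic_frac = 0.15,
                 strand_flip_frac = 0.2, swap_frac = 0.2,
                 seed = 20250600 + match(name, names(partners)))
  rcfg$n_out <- n_focal
  rsim <- simulate_pair(rcfg)
  rsim$exposure$trait_label <- name
  rsim$outcome$trait_label <- "focal"
  write_sumstats(rsim$exposure,
                 file.path(out_dir, sprintf("%s_exposure.tsv", name)))
  write_sumstats(rsim$outcome,
                 file.path(out_dir, sprintf("focal_out_for_%s.tsv", name)))
  write_table(rsim$truth$snps,
              file.path(out_dir, sprintf("truth_reverse_%s.tsv", name)))
}
cat("simulated cohorts written to", out_dir, "\n")
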