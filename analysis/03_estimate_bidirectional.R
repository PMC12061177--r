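#!/usr/bin/env Rscript

# The full bidirectional causal analysis: for each partner trait, run the
# forward (focal -> partner, exposure p < 5e-8) and reverse (partner ->
# focal, relaxed p < 5e-6) pipelines — selection, harmonization, Steiger,
# four estimators, sensitivity battery, one outlier-removal re-run — and
# apply per-direction Benjamini-Hochberg FDR over the five IVW p-values.

library(mrkit)

in_dir <- "results/simdata"
out_dir <- "results/mr"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

partners <- c("acd", "ad", "vad", "ftd", "dlb")
results <- list()
for (name in partners) {
  exposure <- read_sumstats(file.path(in_dir,
                                      sprintf("focal_for_%s.tsv", name)),
                            trait_label = "focal")
  outcome <- read_sumstats(file.path(in_dir, sprintf("%s.tsv", name)),
                           trait_label = name)
  results[[length(results) + 1L]] <- run_pair(
    exposure, outcome, mr_criteria(p_exposure_max = 5e-8),
    direction = "forward", seed = 1000 + match(name, partners),
    presso_n_sim = 1000)
  rev_exposure <- read_sumstats(file.path(in_dir,
                                          sprintf("%s_exposure.tsv", name)),
                                trait_label = name)
  rev_outcome <- read_sumstats(
    file.path(in_dir, sprintf("focal_out_for_%s.tsv", name)),
    trait_label = "focal")
  results[[length(results) + 1L]] <- suppressWarnings(run_pair(
    rev_exposure, rev_outcome, mr_criteria(p_exposure_max = 5e-6),
    direction = "reverse", seed = 2000 + match(name, partners),
    presso_n_sim = 1000))
}
report <- assemble_report(results, expected_per_direction = 5)
write_report_files(report, out_dir)

ivw <- report$estimates[report$estimates$method == "ivw", ]
cat("\nForward IVW results (synthetic, truth in results/simdata):\n")
print(round_report(ivw[ivw$direction == "forward",
                       c("outcome", "n_snp", "or", "or_ci_low",
                         "or_ci_high", "pval", "fdr_p", "significant")]),
      row.names = FALSE)
cat("\nReverse IVW results:\n")
print(round_report(ivw[ivw$direction == "reverse",
                       c("exposure", "n_snp", "or", "or_ci_low",
                         "or_ci_high", "pval", "fdr_p", "significant")]),
      row.names = FALSE)
cat("\nfull tables written to", out_dir, "\n")
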