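#!/usr/bin/env Rscript

# Shape the per-pair diagnostics into the conventional sensitivity table
# (heterogeneity: Cochran's Q p under Egger and IVW; pleiotropy: Egger
# intercept p and MR-PRESSO global p) for the forward direction, and
# summarize per-SNP influence diagnostics.

library(mrkit)

mr_dir <- "results/mr"
sens_path <- file.path(mr_dir, "sensitivity.tsv")
if (!file.exists(sens_path)) {
  stop("run analysis/03_estimate_bidirectional.R first")
}
sens <- utils::read.delim(sens_path)
fw <- sens[sens$direction == "forward",
           c("outcome", "n_snp", "p_q_egger", "p_q_ivw",
             "p_egger_intercept", "p_presso_global")]
for (j in 3:6) fw[[j]] <- round(fw[[j]], 3)
write_table(fw, file.path(mr_dir, "sensitivity_forward_rounded.tsv"))
cat("Forward-direction sensitivity table:\n")
print(fw, row.names = FALSE)

loo_files <- list.files(mr_dir, pattern = "^loo_forward_", full.names = TRUE)
influential <- 0L
for (f in loo_files) {
  tab <- utils::read.delim(f)
  influential <- influential + sum(tab$influential)
}
cat(sprintf("\nleave-one-out: %d influential SNP(s) across %d forward pairs\n",
            influential, length(loo_files)))
cat("tables written to", mr_dir, "\n")
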