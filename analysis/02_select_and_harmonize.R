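#!/usr/bin/env Rscript

# Instrument selection and harmonization audit for each forward pair:
# genome-wide exposure filter, strength (R2/F) filter, outcome-association
# filter, palindrome removal and Steiger directionality. Writes one
# exclusion table per pair and a per-pair selection summary.

library(mrkit)

in_dir <- "results/simdata"
out_dir <- "results/selection"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

partners <- c("acd", "ad", "vad", "ftd", "dlb")
summary_rows <- list()
for (name in partners) {
  exposure <- read_sumstats(file.path(in_dir,
                                      sprintf("focal_for_%s.tsv", name)),
                            trait_label = "focal")
  outcome <- read_sumstats(file.path(in_dir, sprintf("%s.tsv", name)),
                           trait_label = name)
  crit <- mr_criteria(p_exposure_max = 5e-8)
  sel <- filter_by_exposure_p(exposure, crit$p_exposure_max)
  hset <- harmonize_set(sel, outcome)
  hset <- apply_filters(hset, crit)
  hset <- steiger_filter(hset)
  write_table(hset$exclusion_log,
              file.path(out_dir, sprintf("exclusions_%s.tsv", name)))
  counts <- table(hset$exclusion_log$reason)
  summary_rows[[name]] <- data.frame(
    outcome = name,
    n_input = nsnp(exposure),
    n_genomewide = nsnp(sel),
    n_final = nrow(hset$pairs),
    n_palindromic = sum(hset$exclusion_log$reason == "palindromic"),
    n_steiger_false = sum(hset$exclusion_log$reason == "steiger_false"),
    stringsAsFactors = FALSE)
  cat(sprintf("%s: %d input -> %d genome-wide -> %d instruments (%s)\n",
              name, nsnp(exposure), nsnp(sel), nrow(hset$pairs),
              paste(sprintf("%s=%d", names(counts), counts),
                    collapse = ", ")))
}
write_table(do.call(rbind, summary_rows),
            file.path(out_dir, "selection_summary.tsv"))
cat("selection audit written to", out_dir, "\n")
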