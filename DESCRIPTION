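Package: mrkit
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: flexible summary-statistic import with
    validation, allele harmonization with palindromic-SNP removal, instrument
    selection (genome-wide significance threshold, greedy LD clumping,
    per-SNP R-squared/F weak-instrument filter, outcome-association and
    confounder exclusion, Steiger directionality filtering), causal estimation
    by Wald ratio, inverse-variance weighting, MR-Egger regression, the
    weighted median and constrained-maximum-likelihood model averaging
    (cML-MA), a sensitivity battery (Cochran's Q, Egger intercept, MR-PRESSO
    global/outlier/distortion tests, radial MR, leave-one-out), per-direction
    Benjamini-Hochberg FDR reporting, and a seeded synthetic GWAS
    summary-statistic generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
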