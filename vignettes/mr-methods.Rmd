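---
title: "Bidirectional two-sample Mendelian randomization with mrkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample MR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem

Two-sample Mendelian randomization (MR) asks whether an exposure causes an
outcome using only GWAS summary statistics from two (possibly
non-overlapping) studies. Genetic variants serve as instrumental variables
(IVs) under three assumptions: the variant is associated with the exposure
(relevance), it is independent of exposure-outcome confounders
(independence), and it affects the outcome only through the exposure
(exclusion). `mrkit` implements the full workflow for a bidirectional
design — a focal trait analysed as exposure against a panel of partner
traits and, with a relaxed instrument threshold, as outcome — of the kind
used to study psychiatric-neurodegenerative comorbidity (e.g. a
schizophrenia-scale GWAS against all-cause dementia, Alzheimer's disease,
vascular dementia, frontotemporal dementia and dementia with Lewy bodies).

## Instrument selection

The selection chain is a sequence of per-SNP predicates with a complete
audit trail:

1. **Exposure association.** Keep SNPs with exposure p below 5e-8
   (forward); the reverse direction conventionally relaxes this to 5e-6
   when few SNPs reach genome-wide significance.
2. **LD clumping.** Greedy: order by ascending exposure p (ties broken by
   ascending rsID so runs are deterministic), keep the best SNP, remove
   all SNPs within 10,000 kb with r² ≥ 0.001 to it, repeat. LD comes from
   a user-supplied matrix or pairwise table — the package never queries a
   remote panel, so runs are reproducible offline. Unlisted pairs count as
   unlinked, and the window never spans chromosomes.
3. **Instrument strength.** Per-SNP variance explained and F-statistic:

   $$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2,
     \qquad F = \frac{R^2 (N-2)}{1-R^2},$$

   with SNPs below F = 10 removed as weak. R² here is per-SNP, not
   cumulative: a cumulative R² would make each SNP's F depend on how many
   other instruments were selected, which is incompatible with a per-SNP
   removal rule. Both formulas need the effect-allele frequency; SNPs with
   missing EAF are excluded (reason `no_eaf`) rather than imputed, the
   conservative choice. For binary traits, N is cases + controls; no
   effective-sample-size correction is applied.
4. **Outcome association.** SNPs with outcome p < 5e-5 are removed — a
   variant strongly associated with the outcome in its own right is a poor
   instrument.
5. **Harmonization.** Exposure and outcome effects are placed on the same
   effect allele: matching alleles pass through; swapped alleles negate
   the outcome effect and reflect its allele frequency (1 − EAF, with a
   missing EAF staying missing); strand-complement pairs are recoded
   first, then the same rule applies. Palindromic SNPs (A/T, C/G) are
   **always** removed — no frequency-based rescue — because their strand
   cannot be resolved from the alleles; we prefer fidelity of the retained
   set over data retention. Non-palindromic complements are recoded rather
   than dropped, and the recode is visible in the audit log.
6. **Steiger directionality.** A SNP that explains more variance in the
   outcome than in the exposure likely acts in the reverse direction. We
   compute R² on each side by the same formula and compare the implied
   absolute correlations r = √R² with a one-sided Fisher-z test,
   $z = (\operatorname{atanh} r_{exp} - \operatorname{atanh} r_{out}) /
   \sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}$; a SNP is kept only when the
   direction is significantly TRUE at 0.05. SNPs missing an EAF on either
   side cannot be tested and pass with a warning. A pooled-set mode
   (pooled correlation √ΣR² per side, median sample sizes) is available
   for a single set-level summary; the filter itself acts per SNP. The
   exact variant of the Steiger statistic is a package choice — the
   correlation could also be derived from p and n — and is documented
   here rather than asserted as canonical.
7. **Confounder exclusion.** A user-supplied SNP list (e.g. variants
   associated with smoking, drinking, hypertension, diabetes or body mass
   index in a GWAS-catalog lookup) is removed with reason `confounder`;
   the package deliberately has no online catalog client.

The pipeline applies the strength/outcome/confounder predicates after
harmonization (they are flip-invariant, so the surviving set is identical
to applying them before) so that one exclusion log covers every SNP
exactly once: input count = survivors + Σ per-reason exclusions, an
invariant the tests enforce.

## Estimators

Let $\hat\beta_{Xj}, \hat\beta_{Yj}$ be harmonized per-SNP effects with
standard errors $\sigma_{Xj}, \sigma_{Yj}$, and $\hat\theta_j =
\hat\beta_{Yj}/\hat\beta_{Xj}$ the Wald ratio with first-order
delta-method SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ (the second-order term is
deliberately omitted and documented, as both conventions exist in the
field).

* **IVW.** Inverse-variance weighted mean of the Wald ratios. The default
  is the multiplicative random-effects model: the fixed-effect SE is
  inflated by $\max(1, \sqrt{Q/(L-1)})$ with Q Cochran's heterogeneity
  statistic. This is the robust default; the fixed-effect variant is a
  flag away. One instrument falls back to the Wald ratio, flagged.
* **MR-Egger.** Weighted least squares of outcome on exposure effects
  with a free intercept (weights $1/\sigma_{Yj}^2$), after orienting all
  pairs so $\hat\beta_{Xj} \ge 0$ — the intercept is
  orientation-dependent, so a fixed convention keeps results
  deterministic. The slope is the causal estimate; the intercept and its
  test quantify directional pleiotropy. Both SEs carry the
  $\max(1, \sqrt{RSS_w/(L-2)})$ inflation.
* **Weighted median.** The weighted 50th percentile of the ordered
  ratios (linear interpolation between the straddling order statistics),
  consistent when valid instruments carry at least half the weight. Its
  SE comes from a seeded parametric bootstrap (default 1000 resamples of
  each ratio from its normal). The bootstrap SE is mildly conservative —
  in our calibration the 95% CI covers ~97% and the nominal-0.05 test
  rejects ~2.5-3% under the null — a known property of this estimator's
  standard error, reported as-is.
* **cML-MA.** Constrained maximum likelihood with model averaging. For
  each candidate number K of invalid instruments we minimize
  $\sum_j (\hat\beta_{Yj} - \theta b_j - r_j)^2/\sigma_{Yj}^2 +
  (\hat\beta_{Xj} - b_j)^2/\sigma_{Xj}^2$ with at most K nonzero direct
  effects $r_j$, by coordinate iteration: given θ the K SNPs with the
  largest profiled squared standardized residuals
  $(\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2/(\sigma_{Yj}^2+\theta^2\sigma_{Xj}^2)$
  get free $r_j$; given the support, $b_j$ is profiled and θ updated in
  closed form, to tolerance 1e-8 or 200 iterations (non-convergent K are
  dropped with a warning). Models are averaged with weights
  $\propto e^{-BIC_K/2}$, $BIC_K = \mathrm{deviance}_K + K\log L$, and
  the averaged variance adds between-model dispersion to the per-K
  curvature-based variances. Only the BIC variant is implemented (no
  data-perturbation averaging); p-values are normal-approximation
  throughout, and the BIC-best support is reported so a planted outlier
  can be identified. K defaults to the full grid 0..L−2. Note that on
  noiseless data all deviances vanish and the BIC weights decay
  geometrically in K, so K = 0 receives the largest — not all — weight.

All 95% CIs are normal-theory $\hat\beta \pm 1.96\,\hat{se}$, and effects
convert to odds ratios as $e^{\hat\beta}$ with
$e^{\hat\beta \pm 1.96\hat{se}}$ bounds.

## Sensitivity battery

* **Cochran's Q** under IVW (df = L−1) and Rücker's Q′ about the Egger
  fit (df = L−2), both against chi-square.
* **MR-PRESSO.** Observed residual sum of squares about leave-one-out
  IVW slopes, compared with a seeded parametric simulation
  (default 1000 replicates; these defaults are package defaults, labelled
  as such in outputs). Empirical p-values use an add-one numerator, so
  they are never exactly zero and are bounded below by 1/(n_sim+1).
  Per-SNP outlier p-values are Bonferroni-corrected by L; the distortion
  test compares the outlier-free estimate against removals of equally
  many random SNPs and is reported as not-applicable when no outlier is
  flagged.
* **Radial MR.** Per-SNP contributions $q_j$ to heterogeneity about the
  radial (weighted through-origin) slope, each on chi-square df 1.
  First-order weights are the default so that $\sum_j q_j$ equals the IVW
  Cochran Q exactly — an identity the tests assert — with modified
  second-order weights behind a flag.
* **Leave-one-out.** IVW on every L−1 subset; a SNP is flagged
  influential when its omission flips the estimate's sign or moves its
  p-value across 0.05.

When MR-PRESSO or radial MR flags outliers, the pipeline removes them and
re-runs estimation and sensitivity exactly once (a single
discard-and-re-execute pass), reporting both passes and logging the
removals.

## Multiple testing and reporting

IVW p-values are adjusted by the Benjamini–Hochberg step-up within each
direction: the five forward analyses form one FDR family (m = 5) and the
five reverse analyses another. This family structure — per-direction, not
pooled — is the one consistent with published adjusted values of the
motivating analysis (0.027·5/3 = 0.045; pooling across directions would
not reproduce it). A causal claim requires both the raw and the adjusted
IVW p below 0.05. Other estimators are reported unadjusted; they serve as
concordance checks rather than primary tests. Display tables round OR and
p to 3 decimals; machine-readable tables keep full precision.

## The synthetic generator

`simulate_pair()` draws, per SNP: an allele frequency uniform on
(0.1, 0.9); a true exposure effect from a half-normal with scale 0.05,
reported on the exposure-increasing allele (a fixed orientation is what
makes *directional* pleiotropy a meaningful regime — with sign-symmetric
instrument effects a constant-mean direct effect cancels from every
slope-based estimator); optionally resampled until the true-effect F
statistic reaches a requested floor; and a direct effect $r_j$ on the
outcome that is zero for valid SNPs and otherwise balanced (mean 0),
directional (mean 0.05 by default), or correlated with instrument
strength (violating InSIDE, correlation 0.7). Observed effects add noise
with the standardized-trait approximation
$se = 1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})\,n}$ — adequate for
exercising estimator mathematics, though it ignores case-control
imbalance, so simulated SEs for very unbalanced cohorts are optimistic.
Configurable fractions of SNPs are written as palindromic, on the
complementary strand, or allele-swapped in the outcome file, so the
harmonization path is exercised end to end; an optional LD-block mode
(within-block r² 0.9, members within 50 kb) exists solely to exercise
clumping, since post-clumping instruments are modelled as independent.
Presets carry the case+control totals of the motivating cohorts
(schizophrenia 130,644; all-cause dementia 348,676; Alzheimer's disease
487,511; vascular dementia 436,182; frontotemporal dementia 3,024;
dementia with Lewy bodies 6,618). Identical configuration and seed give
bit-identical output, and the generator restores the caller's RNG state.

What passing tests on this generator do **not** show: robustness to LD
misspecification, to sample overlap between the two studies, to
population stratification, or to the binary-trait noncollapsibility of
odds ratios — none of which the generator emulates.

## Study sizes used in the checks

The simulation studies in `analysis/05_calibration_study.R`, the test
suite and `scripts/acceptance.R` use: recovery and coverage at θ = 0.1
with L = 50 instruments, n = 100,000 per side and per-SNP F ≥ 30 (500
replicates in the test suite, 200 in the analysis and acceptance
scripts); type-I error at θ = 0 (1000 replicates in the suite, 400 in
the scripts); 30% invalid instruments with directional pleiotropy of
mean 0.05 for the robustness comparison; and a 10-SE planted outlier in
L = 20 for detection rates (100 runs in the suite, 50 in the scripts).
Measured this way, all four estimators have |mean bias| below 0.01 and
coverage between 0.92 and 0.98; IVW, Egger and cML-MA hold the 0.05 test
between 0.03 and 0.07 under the null, while the weighted median is
slightly conservative as noted above. Under directional pleiotropy the
weighted median's bias is an order of magnitude below IVW's and the mean
Egger intercept matches the planted mean direct effect
(0.3 × 0.05 = 0.015).

## Numerical and degenerate-input conventions

Missing values are the literal "NA" (case-insensitive) or an empty
field; only EAF may be missing. Alleles are restricted to single bases
A/C/G/T; anything else is dropped as `non_snp`. R² is capped just below
1 so F stays finite. A single surviving instrument yields the Wald
ratio, zero or one survivors mark the pair not-estimable rather than
erroring, and an exactly-fitting Egger regression keeps a finite SE via
the inflation floor of 1. Clumping ties are broken by rsID. The
weighted-median and MR-PRESSO seeds are mandatory in the pipeline
configuration; every stochastic output is bit-reproducible from (input,
seed).

## Known limitations

Proxy-SNP lookup for instruments missing in the outcome is deliberately
absent, as is allele-frequency-based inference of strand for palindromic
SNPs, multi-allelic reconciliation, VCF-encoded summary statistics,
remote LD/clumping services and GWAS-catalog confounder lookup. MR-RAPS,
mode-based estimators and multivariable MR are out of scope. The cML-MA
implementation averages over BIC only; a data-perturbation variant would
add robustness at several times the computational cost.
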