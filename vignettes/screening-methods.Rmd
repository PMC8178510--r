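---
title: "Methods: cis-eQTL mapping, Mendelian randomization and the candidate funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-eQTL mapping, Mendelian randomization and the candidate funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-cohort generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The screening problem

GWAS risk loci for lung disease are overwhelmingly non-coding, so their
phenotypic effects are presumed to run through expression regulation. The
pipeline operationalizes one specific causal chain — germline variant →
miRNA abundance → mRNA target → clinical phenotype — as a sequence of
testable regressions over a tumor cohort with matched genotypes, small-RNA
and mRNA expression, copy-number, methylation, and survival follow-up.

## Stage models and assumptions

**Genotype QC.** Imputed variants are filtered on info score (> 0.7), MAF
(> 5%, computed as mean dosage / 2 over non-missing calls), per-call
maximum genotype probability (> 0.7; failing calls are set missing rather
than discarding the variant, keeping this criterion distinct from the
info-score criterion), and a Hardy-Weinberg chi-square test (p > 1e-6) on
best-guess genotypes. Tag-SNP expansion collects panel variants within
1 Mb and composite LD r² > 0.5 (squared Pearson correlation of unphased
dosages — phase is not available after imputation filtering, so
haplotype-EM r² is deliberately not attempted). Ancestry assignment
standardizes shared-variant dosages, fits a PCA on the merged
cohort+reference matrix, and labels each cohort sample by majority vote of
its 5 nearest reference samples in the PC1–PC2 plane, ties broken by
smallest mean distance. The 5-NN rule is our choice; only the "top two
principal components" part of the procedure is externally fixed.

**cis-eQTL scan.** For each (SNP, miRNA) pair whose transcription start
(annotated start on +, end on −) lies within 1 Mb of the SNP, ordinary
least squares fits

    miRNA = b0 + b1 G + b2 Age + b3 Sex + b4 CNV + b5 CpG + e.

Assumptions: Gaussian residuals (exact t inference), additive allele
dosage effects, and a single numeric coefficient for each of CNV
(−1/0/+1) and CpG (0–3) — the ordinal coding mirrors the one-coefficient
form of the model, not a dummy expansion. Missingness is handled
pairwise-complete per pair, and the per-pair sample count is reported.
Multiplicity is controlled by Benjamini–Hochberg across **all tested
pairs jointly** at FDR 0.1; per-miRNA adjustment would be an alternative
universe and is left to the caller by filtering the output. The
implementation solves each pair directly by QR decomposition; the test
suite pins it to an independent `lm()` refit at 1e-8 relative tolerance
(measured agreement ~4e-15).

**Mendelian randomization.** With a significant eSNP as instrument, the
causal effect of the eMiR on each candidate mRNA is the Wald ratio
cov(G, mRNA)/cov(G, miRNA), identical to two-stage least squares for a
single instrument (asserted to 1e-10 in tests). Its standard error uses
the delta-method/IV-sandwich form with structural residuals. Validity
assumptions are the usual three: the instrument is associated with the
exposure (screened by the first-stage F = (n−2)R²/(1−R²) under BH FDR
< 0.05 — "significant genetic instrument" is read as rejecting the
zero-first-stage null, and no F > 10 rule of thumb is added), affects the
outcome only through the exposure, and shares no confounder with the
outcome. A first-stage covariance that is *numerically* zero (relative
tolerance 1e-10) raises an undefined-instrument error; a statistically
weak but finite first stage passes through with its small F, because the
funnel, not the estimator, is the arbiter of instrument strength.

**Candidate funnel.** Criteria run in fixed order: (a) target-prediction
integrated score ≥ 0.1 (the score arrives as an annotation column; the
prediction database itself is not reimplemented); (b) present calls ≥ 100,
where "present" means non-missing with raw abundance strictly positive;
(c) any IV axis for the gene significant under BH FDR < 0.05; (d)
differential expression with FDR < 0.01 and |log2 FC| > 0.5; (e)
median-split Cox survival screen with FDR < 0.05. BH at stages (c)–(e) is
recomputed within the genes entering the stage, so each stage's
multiplicity universe is what it actually evaluates — the alternative
(global q-values frozen upstream) would let earlier filters change later
stages' meaning silently. A gene with a missing statistic at a reached
stage fails that stage with reason `missing`; it never passes silently.

**Differential expression.** Welch's unequal-variance t-test per feature
on log2 values (the equal-variance test and a paired variant are
available; Welch is the robust default since tumor and normal variances
differ in practice). Features absent in more than 10 samples in either
group are excluded before testing. Fold change is the difference of
group means on the log2 scale.

**Survival.** The Cox partial likelihood with Efron tie handling is
maximized by Newton–Raphson (convergence |step| < 1e-9, max 30
iterations); risk-set sums are computed by descending-time cumulative
sums, so a fit is O(n log n) per iteration. Monotone likelihoods
(complete separation) are detected by a diverging coefficient, capped at
|β| = 15 and flagged. The screen dichotomizes each feature at the cohort
median (strictly-above = high; ties fall low), a deterministic stand-in
for auto-selected split points in online survival tools. Kaplan–Meier
curves and the two-group log-rank test use the standard hypergeometric
variance, with the variance contribution skipped when only one subject
remains at risk.

**2×2 association.** The odds ratio is the cross-product (a·d)/(b·c) with
rows = expression group (high, low) and columns = outcome levels with a
configurable numerator level per characteristic; the Wald p-value from
se = sqrt(1/a+1/b+1/c+1/d) equals the Wald test of a logistic regression
with one binary predictor. Zero cells report OR 0/Inf with a flag and no
p-value; the Haldane–Anscombe +0.5 correction is opt-in, never silent.

## The synthetic cohort generator

The generator forward-simulates exactly the structure the analysis
assumes, so downstream stages can be validated against known truth.

* **Haplotypes and LD.** Each haplotype is a latent Gaussian AR(1) chain:
  z₁ = e₁, zⱼ = r·zⱼ₋₁ + √(1−r²)·eⱼ, allele = 1{zⱼ < Φ⁻¹(pⱼ)}. This
  copula construction keeps every variant's marginal exactly
  Bernoulli(pⱼ) for any correlation r (`ld_decay`), while adjacent-variant
  r² grows monotonically with r. A simpler "copy the previous allele with
  probability r" chain was considered and rejected: with heterogeneous
  allele frequencies it drags each variant's realized frequency toward its
  neighbors', so configured MAFs would not be honored. Diploid dosage is
  the sum of two independent haplotypes.
* **Expression.** miRNA values follow the stage-one regression forward
  (baseline 5 on the log2(RPM+1) scale, covariate coefficients
  age 0.01/yr, sex 0.2, CNV 0.5, CpG −0.3 by default, Gaussian noise
  σ = 1); mRNA values follow the stage-two model with the configured
  trans effects (baseline 8). An optional shared per-sample confounder
  can be added to both, to emulate the regime instrumental variables are
  designed for.
* **Covariates.** Age ~ Normal(65, 8) truncated to [30, 90] (matching the
  usual dichotomy around 65 in clinical tables); sex ~ Bernoulli(0.5);
  CNV categories drawn from {−1, 0, +1} with probabilities
  (0.2, 0.6, 0.2); CpG categories uniform on {0, 1, 2, 3}.
* **Survival.** Exponential event times with per-sample log hazard equal
  to the configured per-feature log HRs applied to standardized mRNA
  expression; independent Uniform(0, c) censoring with c = 3.2 / baseline
  hazard, which gives ≈30% censoring under the null — enough events to
  keep log-rank/Cox screens well powered at the cohort sizes used here.
* **Reproducibility.** All randomness flows from one root seed through
  named per-stage streams (`genotypes`, `covariates`, `groups`, `mirna`,
  `mrna`, `survival`), hashed into independent 32-bit seeds, so identical
  configurations give bit-identical cohorts and stages can be regenerated
  independently.

What the generator does **not** emulate: realistic recombination maps or
population demography (LD is a single-parameter chain), read-level
sequencing noise, library-size artifacts, batch effects, non-Gaussian
expression tails, informative censoring, or correlated CNV/CpG structure
along the genome. Passing tests therefore demonstrate statistical
correctness of the machinery under the assumed generative model, not
robustness to every failure mode of real tumor data.

## Numerical choices and degenerate inputs

* HWE uses the 1-df chi-square on rounded dosages (nearest integer, ties
  to even); monomorphic variants return p = 1 since no departure is
  measurable. The exact test was not used: at the 1e-6 threshold and
  cohort-scale counts the two agree in the rejection region.
* Methylation categories use fixed quartile cutpoints (0.25, 0.5, 0.75)
  of the beta scale, boundaries assigned to the lower category —
  data-driven quantiles would make categories cohort-dependent and
  irreproducible across runs. CNV calls use a symmetric ±0.3 threshold on
  the segment log2 ratio, overridable, and pre-categorized input is
  accepted verbatim.
* "Absent" expression is RPM exactly 0 — the only unambiguous reading for
  count-derived RPM. Outlier masking computes mean/SD once on all
  non-missing values (single pass, no re-iteration), and whether such an
  exclusion should remove the whole individual instead of the single
  entry is genuinely ambiguous; per-entry masking was chosen as the less
  destructive reading.
* Reporting order of associations is deterministic: p ascending, ties by
  |t| descending, then SNP and feature identifiers.
* Coordinates are 1-based inclusive at every file interface; the cis
  window test |SNP − anchor| ≤ window is inclusive at the boundary.
* Constant genotypes, rank-deficient covariate designs and undefined LD
  (constant dosage) are skipped or errored per item with recorded
  reasons; the scans continue.

## Problem sizes

The test suite and the acceptance script validate at sizes chosen to
make Monte-Carlo margins meaningful on a single core: 3 cohorts × ~500
pairs for the scan/OLS identity, 200 null cohorts × 100 pairs for FDR
calibration, 100 replicates at n = 227 (MAF 0.3, β1 = 0.8, σ = 1) for
power and bias, 100 confounded cohorts at n = 5000 for the IV
comparison, and 100 replicates at n = 1000 with ~30% censoring for
hazard-ratio recovery. These mirror the cohort scale of the motivating
use case (a 227-sample tumor cohort) where a planted effect of that size
is called essentially always.

## Known limitations

Trans-eQTL scanning, multi-instrument MR estimators (Egger, weighted
median), colocalization, kinship/mixed-model association, competing
risks and multivariable Cox model selection are out of scope. The
weak-instrument screen tests only the first-stage association; it cannot
detect pleiotropy or confounded instruments. FDR is controlled per stage
and per run; re-running the funnel with different candidate sets changes
the multiplicity universe by design.
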