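---
title: "molqtl: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molqtl: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`molqtl` re-implements, at desk scale and with planted ground truth, the
statistical core of a multi-tissue molecular-QTL (molQTL) study: normalized
molecular phenotypes and genotypes in, cis/trans/interaction QTL calls,
tissue-sharing statistics, and GWAS integration (enrichment, colocalization,
summary-based Mendelian randomization, TWAS, cross-species meta-TWAS) out.
Everything runs on seeded synthetic cohorts; nothing in the package depends
on the original study's raw data. The package deliberately excludes read
processing, genotype imputation, lncRNA/enhancer discovery, methylation,
Hi-C and single-cell deconvolution: annotations, TAD intervals and cell-type
scores are consumed as inputs.

# The synthetic world

The generators state a world once; tests measure the pipeline against it.

**Genotypes.** Diploid dosages for discrete breeds. Population allele
frequencies are uniform on `maf_range` (default 0.1–0.5) and drifted per
breed by `breed_af_drift` (default 0.1; 0.2 gives PC1-separable breeds).
Haplotypes follow a Gaussian-copula AR(1): the latent correlation between
markers `d` bp apart is `exp(-d/ld_decay)` (default half-distance 50 kb).
One parameter, analytically checkable, and it produces the monotone LD decay
the clumping, HEIDI and fine-mapping steps assume. Realized MAF is floored
at 0.05 by resampling, because the mapping contract filters at MAF 0.05 and
a fixture variant that fails its own filter tests nothing. Each sample also
carries a continuous ancestry proportion (Beta(8,2) for breed 1, Beta(2,8)
otherwise); this is the "breed enrichment" context for interaction QTL. The
variant panel (positions, frequencies) depends only on the seed, so oracle
cohorts of any size can be drawn on an identical panel.

**Expression.** Log-normal–Poisson counts:
`log2 mu = baseline + slope*dosage + loadings*factors + N(0, noise_sd)`,
scaled by log-normal library sizes and Poisson-sampled. The planted slope is
therefore a log2 allelic fold change, directly recoverable by OLS on log2
counts — the property the aFC and slope-recovery tests rely on. Baselines
are `N(8, 1)` on the log2 scale (~256 counts), so Poisson noise is small
relative to the biological `noise_sd = 0.5`. The first hidden factor is
deliberately correlated (0.8) with ancestry: batch and population are
confounded in real cohorts, and this is what makes an uncorrected scan
genomically inflated while the corrected scan stays calibrated — a property
the tests assert. Interaction effects are planted on variants with MAF ≥
0.15 so the context-stratified MAF filter keeps them testable.

**Splicing.** Intron clusters of 2–4 introns per simulated gene; per-sample
cluster totals are log-normal–Poisson and split multinomially. A planted
sQTL shifts the first intron's share on the logit scale; planted clusters
have exactly two introns so the logit of the first intron's fraction shifts
by exactly the planted amount, giving a closed-form oracle.

**GWAS.** By default z-scores are drawn from the regression-with-summary-
statistics model, `z ~ MVN(R lambda, R)` with `lambda = sqrt(n) beta_std`;
an individual-level mode (fresh cohort on the same panel, marginal OLS z)
serves as the oracle for this shortcut. Causal effects are rescaled to the
requested locus heritability ignoring causal–causal LD, exact for the
mutually unlinked causal sets used throughout.

**What a green test does not establish.** The generators have no
recombination hotspots, no admixture beyond discrete breeds plus a
continuous ancestry covariate, no realistic count overdispersion beyond
log-normal–Poisson, and independent noise across features given the
factors. Calibration and recovery results transfer to real data only to the
extent these simplifications are benign for the statistic under test.

# Phenotype preparation

The expression pipeline order is fixed: counts → TPM → expression filter
(TPM < 0.1 or counts < 6 in strictly more than 80% of samples) → TMM →
rank-based inverse normal transform. The splicing pipeline: intron counts →
PSI → zero-fraction filter (> 50%), unique-value floor (`max(10, 0.1 n)`),
low-complexity z-rule, cluster-size floor → per-intron z-score → INT.
Thresholds are strict inequalities as stated by their sources.

Choices worth flagging:

* **TMM** is implemented in-package (30% M-trim, 5% A-trim,
  inverse-asymptotic-variance weights, reference = sample whose 75th count
  percentile is closest to the mean); the tests verify it against both
  `edgeR::calcNormFactors` and a naive brute-force re-implementation to
  1e-8. It is a tested contract here, not a convenience call.
* **INT offset** is `(rank − 0.5)/n`, matching the cis-QTL tool family this
  pipeline mirrors; Blom's `(rank − 3/8)/(n + 1/4)` is available via an
  argument.
* **Hidden factors** are a probabilistic-PCA surrogate (SVD of the
  feature-standardized matrix, factors ranked by eigenvalue) for the
  variational factor model used in the original tool chain. Downstream code
  only consumes the factor matrix, and for covariate correction only the
  subspace matters; the surrogate is deterministic, which the tests need.
  This is a documented deviation.
* **Missing PSI** (zero cluster total in a sample) is imputed to the
  intron's mean over defined samples and flagged, keeping design matrices
  complete. The exact standardization used by the original splicing
  pipeline is not restated anywhere; per-intron z-scoring followed by INT
  is assumed.
* **TAU** uses Yanai's definition on `log2(TPM + 1)` medians; the source
  figure names TAU without printing a formula, so the field-standard
  definition is adopted.
* **Genotype PCs**: 5 for cohorts under 200 samples, 10 otherwise, as
  stated.

# Cis-QTL mapping

The scan engine residualizes phenotypes and genotypes on the covariates and
works with correlations; by Frisch–Waugh–Lovell this equals the full joint
regression (tested to 1e-8). Nominal p-values use `t` with
`n − n_covariates − 2` degrees of freedom; the "effective degrees of
freedom" correction some tools estimate is omitted, and the calibration
tests justify that at these sample sizes. The cis window is ±1 Mb of the
TSS, inclusive; MAF ≥ 0.05 and MAC ≥ 6 within the analyzed samples.

**Permutations.** Per feature (or feature group for splicing), sample labels
of the residualized phenotype are permuted; each permutation records the
window-wide minimum p. Permutation stops after 100 exceedances of the
observed minimum or 1,000 permutations (both configurable; the source does
not state its bounds). A Beta distribution is fitted to the minima by
maximum likelihood (BFGS on log-shapes from a method-of-moments start; tied
minima separated by machine epsilon) and the beta-approximated empirical
p-value is its CDF at the observed minimum. Group mode permutes once per
group, preserving intra-cluster correlation — chosen because the source
does not state whether its grouped permutations re-permute per intron; with
singleton groups the two modes are bit-identical (tested). Per-feature
seeds are derived from the feature id, so results are independent of
evaluation order.

**Two-layer FDR.** BH across the beta-approximated empirical p-values;
eMolecules at q < 0.05; the genome-wide empirical threshold `pt` is the
empirical p of the feature whose q is closest to 0.05 (ties toward the
smaller p — the source states no tie rule); per-feature nominal thresholds
are `qbeta(pt, shape1, shape2)`. Acceptance tests verify the realized
false-discovery proportion stays within 1.5× the nominal rate.

**Conditional signals** use forward–backward stepwise scans at the
per-feature nominal threshold, capped at 10 signals, with collinear
candidates dropped. **Fine-mapping** is single-causal Wakefield ABF
(prior sd 0.15 on the standardized-effect scale, sampling variance `1/n`
when a sample size is supplied); this replaces the sum-of-single-effects
and deterministic-approximation fine-mappers of the original study, which
are out of desk scale. PIPs are normalized BFs; the same ABFs feed
colocalization.

# Interaction QTL

`phenotype ~ genotype + context + genotype:context + covariates` per cis
pair, BH per context. The stability filter (MAF ≥ 0.05 within both context
halves) is a package choice — the source does not state its interaction
filter — and prevents leverage artifacts from variants that are rare in one
half of the context range. ASE-based validation is out of scope; planted
recovery tests stand in.

# Multi-tissue statistics

Fixed-effect meta-analysis is inverse-variance weighting. Tissue m-values
marginalize over all `2^T` activity configurations with a shared effect
`mu ~ N(0, 0.2^2)` across active tissues (Sherman–Morrison closed form per
configuration); exact enumeration up to `T = 12`, self-normalized
importance sampling above (proposal: independent Bernoulli from
single-tissue posteriors), verified against forced enumeration at `T = 14`
to within 0.05. This replaces both the MCMC m-value implementation and the
empirical-Bayes covariance-learning approach of the original study; the
activity cutoff m > 0.7 follows the stated convention. Priors
(`prior_active = 0.5`, effect sd 0.2) are exposed because the original run's
values are unstated.

π1 is Storey's grid estimator with cubic smoothing, evaluated at the
largest λ and clipped. The Rand index is the unadjusted pair-counting
version (adjusted behind a flag); k-means uses 50 seeded restarts per k
with the seed derived from k only, so identical data types yield identical
labels. Note one defect in the build contract's worked example: for the
4-object clusterings {a,a,b,b} vs {a,b,b,b}, explicit pair enumeration
gives 3 agreeing pairs out of 6 (RI = 0.5), not 4/6; the tests assert the
enumerated value.

# GWAS integration

Meta-GWAS combines cohorts by sample-size-weighted z. Loci are greedy
1-Mb distance clumps below lead p 1e-5 (LD-block clumping is accepted as an
external override; distance clumping is transparent and deterministic).
The "comparable level" enrichment scaling converts each tissue's gene-lead
p-values to 1-df chi-squares and rescales them so the median equals λ = 10
times the null median — one concrete reading of a tersely described
procedure, flagged as such. Colocalization uses the five-hypothesis ABF
posterior with priors (1e-4, 1e-4, 1e-5) and reports RCP = PP4; whether
the original hierarchical-prior method aggregates beyond PP4 is out of
scope. SMR is `T = z_e^2 z_g^2 / (z_e^2 + z_g^2)` with exposure
instruments at p < 1e-5 and BH within strata; HEIDI compares Wald ratios
of variants with 0.05 ≤ r² ≤ 0.9 to the top variant (the original method's
window, unstated in the study itself), capped at 20 by eQTL significance,
with a Satterthwaite-scaled chi-square on the correlated deviations —
calibrated to retain ~95% of single-causal simulations. TWAS trains
elastic-net models (mixing 0.5, inner 5-fold CV over glmnet's penalty
path; the study names the model class but not the grid) retained at
ρ_cv > 0.1 and p < 0.05; summary association follows the standard
weight–sigma–z formula and the multi-tissue combination projects onto
principal components of the predicted-expression correlation with an
eigenvalue-ratio cutoff of 30.

# Cross-species comparison

Ortholog effect correlations use Pearson on absolute effects (signed
available via flag; the study's Methods specify absolute) with a
permutation null that shuffles the ortholog map — preserving each species'
marginal effect distribution — and BH at FDR 10%. Meta-TWAS combines
per-gene z with sample-size weights `(n_a z_a + n_b z_b)/sqrt(n_a^2+n_b^2)`;
the weight vector has unit norm, so the statistic is standard normal under
the joint null for any sample sizes (tested by KS at 10,000 draws).
Case-control cohorts enter through `n_eff = 4/(1/cases + 1/controls)`.
The ortholog generator builds |effects| from shared and idiosyncratic
half-normal components, which realizes any absolute-effect correlation in
[0, 1] exactly; negative values are not representable by this construction
and are rejected.

# Numerical and degenerate-input policy

Beta MLE falls back to method-of-moments when the optimizer fails; tied
permutation minima are jittered by machine epsilon. Rank-deficient
covariates error, naming the collinear columns. Monomorphic variants are
excluded before scanning; all-zero samples and all-zero features error or
flag rather than propagate NaN. Every stochastic function takes a seed and
restores the caller's RNG state, and seeds derived internally stay below
2^31.

# Limitations

Single-causal assumptions (ABF, colocalization) are wrong for loci with
allelic series; the conditional scan partially compensates but the two are
not integrated. The HEIDI variance uses a delta-method approximation that
is slightly anticonservative at small |z_eqtl|. The m-value sampler's
proposal degrades when tissues are many and weakly informative. Enrichment
folds are point estimates against a single matched background draw;
bootstrap sds understate background-sampling variance.
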