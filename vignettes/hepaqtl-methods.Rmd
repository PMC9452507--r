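---
title: "hepaqtl: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepaqtl: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters that
matter, what the synthetic-data generators emulate (and what they do not),
and the choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The pipeline and its data model

The package targets the standard bulk-tissue eQTL resource workflow:
genotype dosages (samples × variants, hard calls 0/1/2 of the minor
allele) and RNA-seq expression (genes × samples, both TPM and read
counts), plus a gene annotation carrying chromosome, TSS, strand, symbol
and biotype. A *cis* pair is a gene and a variant on the same chromosome
with position in the closed interval TSS ± 1 Mb; *trans* pairs are
cross-chromosome. Coordinates are 1-based throughout.

## 2. Sample quality control

Four screens, each a separate function so they can be reordered or
dropped, with the exclusion list the union of all flags (monotone: adding
a screen never un-excludes a sample):

- **Call rate**: samples with genotype call rate strictly below 0.98 are
  excluded.
- **Sex concordance**: sex is called twice — from X-chromosome
  heterozygosity (fraction of dosage-1 calls; males, being hemizygous and
  coded 0/2, sit near 0) and from 2-means clustering of XIST-like and
  RPS4Y1-like expression. A sample is excluded only when its reported sex
  disagrees with *both* calls; an `unknown` call never triggers exclusion.
  The X-heterozygosity threshold is not stated by the procedure this
  reproduces; the default 0.1 sits between the hemizygous-male rate
  (0 + genotyping error) and the female HWE rate (2p(1−p) ≈ 0.3–0.5 for
  common variants) and is configurable. 2-means was chosen over fixed
  expression cutoffs because no cutoffs are stated and the two marker
  genes separate the sexes by orders of magnitude.
- **Duplicates**: pairwise hard-call concordance (fraction of identical
  calls); pairs above 0.95 are flagged. This deliberately replaces full
  IBD estimation — the upstream use is only to catch replicated samples,
  and concordance separates duplicates (≈1) from unrelated samples
  (Σ f_g² ≈ 0.4 at common MAF) by a wide margin. Kinship coefficients are
  out of scope.
- **Swap scan**: the k genes whose best cis variant shows the largest
  |Pearson r| with expression are used to predict each sample's k-vector
  of expression from its genotypes (one simple linear model per gene,
  fitted on all samples — mildly circular, but faithful to the described
  procedure; a leave-one-out mode exists behind `leave_one_out = TRUE`).
  Predicted vectors are correlated against every sample's observed
  expression; a sample whose argmax is not itself flags both samples.
  An eligibility floor |r| ≥ 0.3 prevents noise-driven matching on null
  cohorts (with no floor, a cohort with no true eQTLs would still produce
  a full match matrix of pure noise). k = 100 follows the reproduced
  procedure; the test suite shows that k = 40 leaves visibly thinner
  margins (correlations over k genes have standard error ≈ 1/√k, and one
  in twenty synthetic cohorts produced a false cross-match at k = 40).

## 3. Variant and gene filters, transforms

Variants are dropped iff call rate < 0.95, MAF < 0.01 (strict, so a
variant at exactly 0.01 survives), or exact Hardy–Weinberg p < 1e-6. The
HWE test is the exact enumeration test rather than the chi-square
approximation because a 1e-6 threshold lives deep in the tail, where the
chi-square fails at low MAF. Genes are kept iff at least 10 samples have
TPM strictly above 0.1 and at least 6 reads.

Expression is quantile-normalized to the *average* empirical distribution
across samples (each sample's value at rank r becomes the mean of the
cross-sample order statistics at that rank; ties get average ranks with
linear interpolation), then each gene is inverse-normal transformed:
rank r of n maps to Φ⁻¹((r − 0.5)/n). The (r − 0.5)/n offset is one of
several common conventions; it is symmetric and keeps the extremes
finite. A constant gene vector is an error rather than silently zero.

Covariates are sex, the first genotype principal components (default 3)
and expression principal components standing in for PEER factors
(default 30 capped at n/4). PEER is an external model the upstream
workflow calls rather than defines; PCA is the standard substitute and
downstream stages treat the factors as opaque columns either way. PCs are
sign-fixed (largest-|loading| entry positive) so results are reproducible
across BLAS implementations.

## 4. Association

`cis_scan()` residualizes expression and dosage on the covariates once
and uses the correlation-to-t identity, t = r√(df/(1−r²)) with
df = n − #covariates − 2. This is algebraically the per-pair OLS fit with
intercept, covariates and dosage (Frisch–Waugh); the acceptance suite
checks agreement with an `lm()` refit to 1e-8 on 500 random pairs.
P-values that underflow are floored at 5e-324 and marked, never 0.

`egene_pvalue()` permutes the covariate-residualized expression vector
(genotypes and covariates fixed; covariates are *not* re-residualized per
permutation — the standard fast approximation, stated as such), records
the per-permutation minimum p over the gene's cis variants, and stops
early once `adaptive_stop` (default 100) permutation minima beat the
observed minimum or `max_perm` (default 1000; the upstream scale is 1e6 —
the extrapolation property, not the count, is the contract) is reached. A
Beta(a, b) is fitted to the minima by maximum likelihood from a
method-of-moments start (falling back to moments if the optimizer fails),
and the gene-level p is the Beta CDF at the observed minimum. The direct
empirical p, (1 + hits)/(1 + permutations), is reported alongside; on
null genes the two agree within a factor of two for p > 0.01 (acceptance
criterion 3).

`afc_fit()` fits the "log of linear" allelic fold-change model

  log(TPM + 1) = log(1 + c0 + c1·d) + γ'X + ε

by Gauss–Newton with a damped step and backtracking line search (start
c1 = 0, c0 = exp(mean log(TPM+1)) − 1; feasibility c0 + c1·d > 0 enforced
over the observed dosage range; 100-iteration cap with a convergence
flag). Two numerical points are worth recording. First, the `+1` sits
*inside* the nonlinear term so that noiseless TPM = c0(1 + (c1/c0)d) is
recovered exactly. Second, the nuisance covariates enter centered and
*without* an intercept: with a free intercept the parameters (c0, c1) are
identified only through c1/(1 + c0), because the intercept absorbs the
overall scale — the fold change would then be undefined. aFC is
(c0 + 2c1)/c0 on the TPM scale, reported as log2 and clipped at ±log2(100)
(a 100-fold cap, the convention for this effect-size family). The p-value
is the likelihood-ratio statistic n·log(RSS0/RSS1) against c1 = 0 on one
degree of freedom; its null calibration is verified by simulation.

Trans associations are the same linear model on cross-chromosome pairs,
BH-corrected strictly within the trans family (cis and trans never share
a correction). Significant variants are clumped greedily per gene: sorted
by p, a variant joins an existing region when within 1 Mb of that
region's representative, else seeds a new region. The 1 Mb radius is a
choice — "region" is not defined upstream — and the greedy-by-p rule is
stated exactly so it is reproducible. Clumped representatives then
receive four quality flags (cross-mappability, > 2 regions for one gene,
missing symbol, pseudogene biotype); high-quality means no flags.

## 5. Splicing QTLs

Exon usage for a gene is the samples × exons matrix of count proportions
(zero-total samples marked missing). Genotype groups are rounded dosages,
with groups under 5 samples merged toward the nearest dosage. The test
statistic is the distance-based pseudo-F on Euclidean distances between
usage vectors (between-group over within-group mean squares — the
PERMANOVA construction on compositions), with label-permutation p-values
of the form (1 + exceedances)/(1 + permutations), never exactly zero.
The original splicing-QTL method's Hellinger distance and variance
filters are simplified away: the contract here is calibration and power
on synthetic data, not numerical identity with the external package.

At the scan level the per-gene statistic is the *maximum* pseudo-F over
the gene's cis variants, and the permutation recomputes that maximum, so
the gene-level p already pays for the number of variants tried; BH then
runs across genes. (BH directly on per-variant minima without this
correction is anti-conservative and fails its own null behaviour.)

## 6. Enrichment

Gene-set enrichment is the logistic regression of the per-gene eQTL
indicator (best cis p < 1e-5, strict) on set membership; the membership
coefficient is the natural-log odds ratio and equals the closed-form 2×2
log OR when no cell is empty. Empty cells fall back to the
Haldane–Anscombe 0.5 correction, flagged. The expression-adjusted variant
adds log10(mean TPM + 1) — the log transform is the standard choice for
an expression covariate; the upstream description says only "TPM average
expression level". Confidence intervals are Wald (±1.96·SE), labeled as
such; profile likelihood was not stated upstream and Wald is what the
Cochran's Q weights assume anyway. Heterogeneity across datasets is
Cochran's Q with inverse-variance weights and a Bonferroni factor equal
to the number of sets tested. The `absent_as_null` option reproduces the
microarray-meta convention of counting undetected genes as
non-significant, which demonstrably biases lnOR upward on synthetic data
— it exists precisely so that bias mechanism can be shown.

## 7. Tissue specificity

Tissues are clustered on 1 − Spearman ρ between their gene-wise
cis-eQTL posterior-probability columns, with average linkage. The
liver-specificity score ranks genes within each tissue (ascending
posterior → ascending rank, average ranks for ties — both conventions are
explicit because the upstream text states neither), then
score1 = sum of the two liver ranks, score2 = mean non-liver rank,
specificity = score1/score2, so a gene ranked identically everywhere
scores exactly 2. The score is invariant to any monotone transform of a
tissue's posteriors. Set enrichment on the specificity ordering is a
two-sided Wilcoxon rank-sum test (normal approximation, continuity
correction) of set against complement — a transparent stand-in for the
external GSEA program, testing the same claim ("the set ranks high").

## 8. The omnibus TWAS statistic

Given per-dataset z-score columns z₁,…,z_K over genes, with pairwise
across-gene correlations ρᵢⱼ (Pearson on pairwise-complete rows by
default; Spearman behind a flag), the combined statistic for a gene
observed in dataset subset S is

  z = Σ_{i∈S} zᵢ / √v,  v = Σ_{i∈S} Σ_{j∈S} ρᵢⱼ.

Under the null, Var(Σ zᵢ) = v when ρ is exact, so z is variance-1; with
ρ = I it reduces to the Stouffer combination, and with ρ ≡ 1 and equal
zᵢ = z₀ it returns z₀ — perfectly correlated panels add no evidence.
Missing data is handled by restricting S per gene; dropping a dataset
from the panel and restricting S are verified to coincide. ρ is estimated
on all genes, signal included (the option `exclude_top_signal` trims the
top fraction of |z| rows; default off, since the upstream description
makes no exclusion). If the estimated ρ makes v ≤ 0 for some gene (possible
with strongly negative estimates), the gene is skipped with an explicit
reason rather than emitted with an imaginary scale.

As a final robustness layer the combined z's are linearly rescaled by the
unique affine map sending their empirical 0.25/0.75 quantiles to
∓0.6744898 (the standard normal quartiles, used at that printed precision
by convention): slope = 1.3489796/IQR, intercept centering the quartile
midpoint at zero. Genes with and without missing datasets are rescaled
jointly — a choice; rescaling strata separately would leave sparse strata
with unstable quantiles. Two-sided normal p-values and BH q-values follow.

`calibration_sim()` reproduces the motivating comparison: on fully null
equicorrelated panels the naive Stouffer combiner is inflated (at K = 6,
ρ = 0.5 its variance is understated by a factor (1 + (K−1)ρ) = 3.5,
giving ≈ 30% rejections at α = 0.05), while the corrected statistic stays
within [0.04, 0.06]. The acceptance suite runs this at 10⁴ genes × 20
replicates.

## 9. The synthetic world

The generators are pure functions of a `sim_config` and its seed; every
planted feature is recorded in a truth table whose ids resolve against
the generated matrices.

- **Genotypes**: independent variants, hard calls in Hardy–Weinberg
  proportions at MAF drawn uniformly from `maf_range`; an X block where
  males are hemizygous (0/2). Defaults emulate the reference cohort:
  n = 192 with ≈ 35% females. No linkage disequilibrium is generated by
  default — none of the implemented methods requires an LD model.
- **Expression**: TPM = baseline · (1 + (aFC−1)/2·d) · exp(β·d + ε),
  ε ~ N(0, noise_sd²); baselines log-normal (meanlog 3 ≈ 20 TPM — a
  typical expressed-gene level); counts are TPM times a per-sample
  log-normal library factor, rounded (sufficient for the expression
  filter, which needs both scales but not a realistic count model). One
  XIST-like and one RPS4Y1-like gene carry the sex signal. "Strong"
  planted effects, where the tests need them, are β = 2 on common
  variants (per-gene R² ≈ 0.6) — the regime in which genotype-predicted
  expression identifies a sample, which the swap-scan procedure presumes.
- **Exon usage**: multinomial counts around baseline proportions;
  planted splicing QTLs shift the first exon's proportion by
  shift·d/2, with the baseline drawn mid-range so the full dosage-2
  shift stays inside [0,1]; infeasible shifts are an error.
- **TWAS panels**: null gene rows multivariate normal with unit variances
  and equicorrelation `panel_rho` (valid range (−1/(K−1), 1)); causal
  genes shifted by `causal_shift` in every column; entries masked missing
  completely at random. The correlation level among real reference panels
  is not characterized upstream; `panel_rho` is a free simulation
  parameter, with 0.5 as the working default.
- **Posterior matrices**: a shared gene-quality latent drives all
  tissues, a liver-only latent makes the two liver columns more
  correlated with each other than with any other tissue, and planted
  liver-specific genes get posteriors in [0.95, 1] in liver and [0, 0.05]
  elsewhere.
- **Gene sets**: one enriched set whose membership odds differ between
  eQTL and non-eQTL genes by a configurable log odds ratio, plus random
  control sets.

What a green test does **not** establish: the generators have no LD, no
population structure beyond what a test plants explicitly, no
batch/GC/length artefacts in expression, no realistic count dispersion,
and independent variants — so power figures transfer to real cohorts only
qualitatively, and the multiple-testing burden of a dense genotyping
panel is not represented.

## 10. Numerical conventions

- P-values are never 0: underflow is floored at 5e-324 and marked.
- Permutation p-values are (1 + hits)/(1 + permutations).
- BH q-values use the standard step-up rule with monotonicity; families
  (cis, trans, sQTL, TWAS) are corrected separately by construction.
- PCs and factors are sign-fixed by the largest-|loading| rule.
- All generator and permutation randomness flows from explicit integer
  seeds; sub-streams are derived deterministically and stay below 2³¹.

## 11. Known limitations

Conditional/secondary association signals, colocalization, kinship beyond
duplicate detection, genotype imputation, PEER itself, the multi-tissue
empirical-Bayes model that produces posterior matrices, and TWAS weight
training are all out of scope: the package consumes their outputs where
relevant. The swap scan's in-sample fitting is mildly optimistic by
construction; leave-one-out mode exists but is not the default, for
fidelity to the procedure it reproduces.
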