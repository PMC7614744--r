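---
title: "Methods: developmentally partitioned polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmentally partitioned polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery:
the models, the tunable parameters and their defaults, what the
synthetic cohort emulates (and what it does not), and the numerical
choices made where the design was genuinely open. No empirical claim
is made here that the test suite or `scripts/acceptance.R` does not
itself compute.

## The analysis in one paragraph

Eight psychiatric disorder GWAS are reduced, via LD-score regression
and factor models on the resulting genetic covariance matrix, to three
correlated latent factors of shared risk — neurodevelopmental (NDV),
compulsive (COMP) and mood–psychotic (MP) — each with its own per-SNP
summary statistics. NDV SNPs are annotated to genes, genes are classed
by whether their brain expression peaks before or after birth in each
of six regions, and the NDV polygenic score is partitioned into 6 × 3
region-by-timing scores. Mixed-model regressions of twelve symptom
scales on these scores, with FDR control and quintile odds ratios at
the clinical cutoff, localize the predictive genetic signal in
developmental time and brain space.

## Quality control

Variant filters follow the conventional thresholds: minor allele
frequency ≥ 0.01, missingness ≤ 0.05, Hardy–Weinberg exact p ≥ 1e-5
for genotype panels (INFO ≥ 0.9 for imputed summary statistics). The
HWE test is the conditional exact test on the heterozygote count; its
two-sided p-value sums probabilities of configurations no more likely
than the observed one. Removals are attributed to the first failing
criterion in the order MAF → missingness → HWE, so report counts sum
to the total removed without double counting.

LD pruning (window 50 kb, step 5 kb, r² ≤ 0.5) scans left to right
and drops the later-position member of an offending pair; because the
step never exceeds the window, the stepped sliding windows compare
exactly the pairs within one window of each other, which is how the
window is implemented. PCA outliers are samples beyond 4 SD on any of
the first four components of the standardized dosage matrix (one
pass, no recomputation). Relatedness uses the PLINK-style
method-of-moments IBD estimator; pairs with π̂ > 0.125 are resolved
worst-first by removing the member with more missing data (ties: the
later sample id). The estimator assumes approximately independent
variants, so the pipeline orders pruning before the IBD step.

## LD-score regression and the genomic SEM

LD scores are sums of adjusted squared correlations,
r²_adj = r² − (1 − r²)/(n − 2), over a positional window (default
1000 kb; analyses of the simulated panels use 250 kb, matched to the
maximal extent of simulated LD so that windows add no cross-block
noise terms). Univariate LDSC regresses per-SNP χ² on the LD score
with a free intercept — the slope times M/n is the SNP heritability,
the intercept captures confounding — and bivariate LDSC regresses
z-score products for genetic covariances. Weights follow the standard
scheme (inverse LD score times the squared expected statistic from a
first pass). The sampling covariance V of vech(S) comes from a
delete-one-block jackknife over 200 contiguous SNP blocks; V is
smoothed to positive-definite by eigenvalue flooring at 1e-9 of the
largest eigenvalue when needed (flagged in the result).

The exploratory factor analysis standardizes S to correlation scale,
extracts by minimum residual (uniquenesses optimized so off-diagonal
residuals are least-squares minimal), and rotates obliquely with
promax (power 4) applied to the varimax solution. A fixed
generic-position pre-rotation is applied first because perfectly
balanced planted structures put varimax exactly on a stationary point
of its criterion; the final solution is invariant to this. Loadings
below 0.2 in absolute value are masked from factor definitions.

The confirmatory model (NDV = ADHD, ASD, MDD, TS; COMP = AN, OCD, TS;
MP = BIP, MDD, SCZ; correlated factors, unit factor variances) is fit
by diagonally weighted least squares with weight diag(V)⁻¹ (full WLS
behind `estimator = "WLS"`). The test statistic is Browne's
residual-based statistic with the full V, asymptotically χ² on
p* − q degrees of freedom regardless of the fitting weights — for the
default eight-indicator model, χ²(15). CFI is computed against a
free-variances independence model, SRMR on correlation-scale
residuals, AIC as χ² + 2q, and parameter standard errors by the
sandwich formula.

The common-factor GWAS treats each SNP's standardized effects on a
factor's indicators as SNP–indicator covariances augmenting S and
solves the SNP → factor path conditional on the measurement model
(loadings and residual variances fixed at the SNP-free solution) by
weighted least squares per factor cluster. This closed form
reproduces the path algebra exactly (equal loadings λ and equal
indicator betas b give factor beta b/λ), keeps per-SNP costs trivial,
and matches the practice of holding the measurement model fixed while
scanning millions of SNPs. SNPs missing from any indicator of a
factor are emitted as missing and counted.

## Gene-level tests

SNPs are annotated to genes with strand-aware windows — 35 kb
upstream, 10 kb downstream of the transcribed interval — so a
plus-strand gene (s, e) claims [s − 35 kb, e + 10 kb] and a
minus-strand gene [s − 10 kb, e + 35 kb]; `ignore_strand = TRUE`
applies the plus-strand window everywhere. The gene statistic is the
mean χ² of the gene's SNPs. Under the null, k·T follows the mixture
Σ λᵢ χ²₁ with λᵢ the eigenvalues of the SNPs' dosage correlation
matrix (ridge 1e-6 before decomposition); p-values use a
moment-matched gamma (Satterthwaite) approximation, with a
Monte-Carlo alternative (`method = "montecarlo"`) for validation. For
one SNP, or independent SNPs, the mixture degenerates to the exact χ²
tail. The gene-property regression converts gene p-values to probit
z-scores and regresses them, per tissue, on that tissue's log
expression covarying average expression, log gene length and log SNP
count; the p-value is one-sided for positive specificity and a
Bonferroni threshold 0.05/n_tissues is reported.

## Developmental partitioning

Expression is analysed as log2(x + 1) (`--no-log` equivalent:
`log_transform = FALSE`). Set-level contrasts use the mixed model
expr ~ prenatal + (1 | gene) + (1 | donor), REML, with prenatal coded
1 so a positive estimate means higher fetal expression; singular fits
drop the offending variance component. Per-gene classification first
averages replicate samples within donor (donors, not samples, are the
independent units), then applies a Welch t-test of prenatal versus
postnatal donor means, BH FDR across all genes in the region, and the
sign/threshold rule: q < 0.05 with positive estimate → prenatal,
negative → postnatal, otherwise continuous. The neocortex (NCX)
region of the atlas is a single aggregated label, mirroring how
cortical sub-areas are averaged in practice.

## Partitioned polygenic scores

Clumping is greedy by ascending p (ties: position, then id) under an
r² ceiling of 0.1 within 250 kb — the window is a conventional
default, configurable. Scores at threshold Pt sum beta × dosage over
SNPs with p ≤ Pt (primary Pt = 1.0, grid 0.001–1.0); swapped-allele
variants count the complementary dosage 2 − d, mismatched variants
are dropped, and missing dosages are imputed as twice the panel
allele frequency. Partitioned scores take, for each of the 18
(region, class) cells, the SNPs annotated to at least one gene of
that class in that region; each subset is clumped independently
(subset-then-clump; `reclump = FALSE` reuses the parent clump), and a
SNP mapping to genes of several classes contributes to every matching
partition. Standardized scores are z-scores per column; quintiles cut
at the empirical 20/40/60/80 percentiles with ties resolved by stable
sample order.

## Association models

Phenotype regressions are REML mixed models with a site random
intercept (plain least squares when only one site is present), age,
sex and five principal components as fixed covariates, and Wald
normal inference on the score term. ΔR² is the increment in marginal
R² — fixed-effects variance over total variance, in the sense of
Nakagawa & Schielzeth — over the covariate-only model; the
conditional version is reported alongside but marginal is primary.
Nested comparisons add a second score to a base-score model and
report the added term's p and the marginal-R² increment; an added
score collinear with the base model yields a zero increment with a
warning. Quintile odds ratios compare top versus bottom score
quintiles by logistic regression on the clinical flag
(Total ≥ 64, inclusive, on the T-score-like scale); without
covariates and with a zero cell the Haldane–Anscombe 0.5 correction
is applied and flagged. An emergent mode drops individuals flagged at
baseline before testing follow-up flags. "FDR" throughout is
Benjamini–Hochberg (via `stats::p.adjust`), with the grid size
declarable when the analysis grid exceeds the p-values supplied.

## The synthetic cohort

The generator's defaults define the study conditions used in the
tests: 2,000 individuals, 5,000 SNPs in LD blocks of 20 at latent
AR(1) ρ = 0.8, 500 genes, eight disorders with heritability 0.4 and
GWAS n = 50,000 each, six regions with 20% prenatal / 23% postnatal
genes (the rough proportions seen in developmental atlases), a
planted pre-versus-post shift of 1.5 donor-level SD, 20 + 20 donors,
causal phenotype effects in prenatally expressed cerebellar genes
explaining 2% of Total-score variance, ten sites contributing 2% of
variance, and CBCL-like scale correlations spanning ~0.3–0.8 with a
weakly coupled (~0.07–0.12) psychosis scale.

Genotypes threshold two independent AR(ρ) latent Gaussian haplotypes
at the allele-frequency quantile, giving exact marginal MAF,
Hardy–Weinberg genotypes by construction, and controllable LD;
blocks are independent and spread across up to 22 chromosomes. GWAS
z-scores are generated analytically: true standardized effects follow
the factor model u = Λg + e scaled to h²/M per SNP, marginal effects
are LD-smeared through the panel's empirical block correlations, and
sampling noise is drawn with that same correlation — so
E[χ²] = 1 + n·h²·ℓ/M holds exactly with respect to the panel's LD
scores and null z-scores carry realistic LD correlation. Phenotypes
mix a standardized causal-partition liability (loading √r² times each
scale's correlation with Total) with a residual covariance chosen so
the total scale correlation matrix equals the configured target even
after site/age/sex effects are added.

For LDSC calibration the package provides a dedicated two-stratum
reference design (`simulate_ldsc_calibration_panel()`): 4,000
isolated variants whose LD score is exactly 1 anchor the intercept,
and 16,000 variants in 1,600 ten-SNP blocks at ρ = 0.95 supply many
independent LD units for the slope. Variance analysis during
development showed that generic AR panels at M = 20,000 leave the
slope dominated by a few hundred effective LD units; the two-stratum
design brings the heritability estimator's seed-to-seed SD to ~0.02,
which is what makes tight recovery checks meaningful at desk scale.
The factor-GWAS recovery check uses a strongly factor-mediated
architecture (pure clusters, loadings 0.9) because recovery of
*factor-level* effects is bounded by the share of each disorder's
genetic variance that the factors carry: with realistic cross-loading
architectures the disorder-specific effects act as irreducible
contamination on any factor-effect estimate.

What the generator does not emulate: realistic human LD maps and MAF
spectra, imputation dosage uncertainty, ancestry admixture (PCs carry
no structure), sample overlap between GWAS (cross-trait intercepts
are null), assortative mating, and longitudinal follow-up waves.
Passing tests therefore demonstrate internal statistical correctness
and recovery under the stated model, not robustness to those
real-data complications.

## Problem sizes and numerical notes

The test suite runs the LDSC recovery at M = 20,000 over 20 planted
and 20 null seeds, the factor-GWAS calibration over 2,000 SNPs, the
gene-test null over 2,000 replicate genes, the timing classification
over 20 seeds of a 300-gene atlas, the end-to-end partitioned-score
contrast over 20 seeds of the default cohort, and the full-null FDR
grid over 50 reduced cohorts — sizes chosen so the whole suite
completes in minutes on one CPU while each check retains the power
its acceptance band requires.

Numerical choices: correlations on standardized, mean-imputed
dosages (pairwise-complete in pruning); eigenvalue flooring for
near-PSD matrices; minres via L-BFGS-B on uniquenesses in
[1e-3, 1]; CFA via `nlminb` with loadings in [−2, 2], factor
correlations in (−0.98, 0.98), residual variances ≥ 1e-8, numerical
central-difference Jacobians, and an SVD pseudo-inverse fallback for
near-singular information matrices; p-values floored at 1e-300;
degenerate cases (saturated models, zero-variance score columns,
genes without scoreable SNPs, empty partitions, singular mixed-model
fits) return flagged, well-defined results rather than errors.
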