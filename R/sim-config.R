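#' Default cross-disorder factor loading matrix
#'
#' Eight psychiatric disorders loading on three correlated latent factors:
#' a neurodevelopmental factor (NDV: ADHD, ASD, MDD, TS), a compulsive
#' factor (COMP: AN, OCD, TS) and a mood-psychotic factor (MP: BIP, MDD,
#' SCZ). Values are plausible standardized loadings for a planted
#' three-factor genetic architecture; MDD and TS are deliberate
#' cross-loaders.
#'
#' @return 8 x 3 numeric matrix with disorder rownames and factor colnames.
#' @export
default_factor_loadings <- function() {
  L <- rbind(
    ADHD = c(0.70, 0.00, 0.00),
    ASD  = c(0.60, 0.00, 0.00),
    MDD  = c(0.50, 0.00, 0.45),
    TS   = c(0.40, 0.50, 0.00),
    AN   = c(0.00, 0.60, 0.00),
    OCD  = c(0.00, 0.70, 0.00),
    BIP  = c(0.00, 0.00, 0.70),
    SCZ  = c(0.00, 0.00, 0.75)
  )
  colnames(L) <- c("NDV", "COMP", "MP")
  L
}

#' Default factor correlation matrix for the three latent factors
#' @return 3 x 3 correlation matrix.
#' @export
default_factor_corr <- function() {
  P <- matrix(c(
    1.00, 0.35, 0.45,
    0.35, 1.00, 0.40,
    0.45, 0.40, 1.00
  ), 3, 3)
  dimnames(P) <- list(c("NDV", "COMP", "MP"), c("NDV", "COMP", "MP"))
  P
}

#' Default 12-scale phenotype correlation matrix
#'
#' Eleven CBCL-like scales (8 syndrome + Internalizing, Externalizing,
#' Total) plus one child-reported psychosis-spectrum scale. The matrix is
#' a single-factor structure r_jk = l_j * l_k whose CBCL pairwise
#' correlations span roughly 0.3-0.8 while the psychosis scale correlates
#' 0.07-0.12 with the others, matching the weakly coupled psychosis
#' measure seen in population cohorts of this age.
#'
#' @return 12 x 12 positive-definite correlation matrix.
#' @export
default_pheno_corr <- function() {
  l <- c(anxdep = 0.62, withdep = 0.60, somatic = 0.55, social = 0.65,
         thought = 0.63, attention = 0.68, rulebreak = 0.66,
         aggressive = 0.72, internalizing = 0.85, externalizing = 0.86,
         total = 0.92, psychosis = 0.13)
  C <- tcrossprod(l)
  diag(C) <- 1
  dimnames(C) <- list(names(l), names(l))
  C
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter the generator needs: genotype panel dimensions
#' and LD structure, the planted cross-disorder factor model behind the
#' eight GWAS, the developmental expression atlas, and the phenotype
#' model. Defaults define the standard desk-scale study conditions used
#' throughout the package's documentation and tests.
#'
#' @param n_individuals number of cohort individuals.
#' @param n_snps number of variants.
#' @param n_genes number of genes in the simulated gene map and atlas.
#' @param ld_block_size SNPs per independent LD block.
#' @param ld_rho within-block adjacent-SNP latent correlation, in [0, 1).
#' @param maf_range length-2 allele-frequency range in (0, 0.5].
#' @param miss_rate fraction of dosages set missing (default 0).
#' @param disorders character vector of disorder labels (default the 8
#'   psychiatric disorders of the cross-disorder factor model).
#' @param factor_loadings disorders x factors loading matrix.
#' @param factor_corr factor correlation matrix (symmetric PD, unit diag).
#' @param h2_per_disorder SNP heritability per disorder, each in [0, 1].
#' @param n_gwas_per_disorder GWAS sample size per disorder.
#' @param regions six brain-region labels.
#' @param prop_prenatal,prop_postnatal per-region fraction of genes with a
#'   planted prenatal / postnatal expression peak (sum must be <= 1).
#' @param expr_effect planted pre-vs-post shift in donor-level SD units.
#' @param n_donors_pre,n_donors_post atlas donors per developmental window.
#' @param pheno_target_corr 12 x 12 target scale correlation matrix (PSD).
#' @param causal_partition length-2 character c(region, class) naming where
#'   true phenotype-causal genetic effects live.
#' @param pgs_effect_r2 variance share of the Total scale explained by the
#'   true partitioned genetic score.
#' @param n_sites number of study sites.
#' @param site_var_prop site random-intercept variance as a share of
#'   phenotype variance.
#' @param seed integer seed fixing all simulation randomness.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 2000,
                       n_snps = 5000,
                       n_genes = 500,
                       ld_block_size = 20,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       miss_rate = 0,
                       disorders = c("ADHD", "ASD", "MDD", "TS",
                                     "AN", "OCD", "BIP", "SCZ"),
                       factor_loadings = default_factor_loadings(),
                       factor_corr = default_factor_corr(),
                       h2_per_disorder = rep(0.4, length(disorders)),
                       n_gwas_per_disorder = rep(50000, length(disorders)),
                       regions = c("CBC", "AMY", "MDTHAL", "STR", "HIP", "NCX"),
                       prop_prenatal = 0.20,
                       prop_postnatal = 0.23,
                       expr_effect = 1.5,
                       n_donors_pre = 20,
                       n_donors_post = 20,
                       pheno_target_corr = default_pheno_corr(),
                       causal_partition = c("CBC", "prenatal"),
                       pgs_effect_r2 = 0.02,
                       n_sites = 10,
                       site_var_prop = 0.02,
                       seed = 1L) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must lie in [0, 1)")
  k <- length(disorders)
  if (nrow(factor_loadings) != k)
    stop("factor_loadings must have one row per disorder")
  if (!isSymmetric(unname(factor_corr)) ||
      any(abs(diag(factor_corr) - 1) > 1e-10) ||
      any(eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("factor_corr must be symmetric positive-definite with unit diagonal")
  if (any(h2_per_disorder < 0 | h2_per_disorder > 1))
    stop("h2_per_disorder entries must lie in [0, 1]")
  commun <- diag(factor_loadings %*% factor_corr %*% t(factor_loadings))
  if (any(commun > 1))
    stop("factor_loadings imply per-disorder genetic variance > 1")
  if (length(regions) != 6) stop("regions must list exactly 6 labels")
  if (prop_prenatal < 0 || prop_postnatal < 0 ||
      prop_prenatal + prop_postnatal > 1)
    stop("prop_prenatal + prop_postnatal must be <= 1 (both non-negative)")
  if (n_donors_pre < 2 || n_donors_post < 2)
    stop("need at least 2 donors per developmental window")
  ev <- eigen((pheno_target_corr + t(pheno_target_corr)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("pheno_target_corr is not positive-semidefinite; ",
         "consider smoothing it with smooth_to_pd()")
  if (nrow(pheno_target_corr) != 12)
    stop("pheno_target_corr must be 12 x 12")
  if (length(causal_partition) != 2 ||
      !causal_partition[1] %in% regions ||
      !causal_partition[2] %in% c("prenatal", "postnatal", "continuous"))
    stop("causal_partition must name a valid (region, timing class) pair")
  if (pgs_effect_r2 < 0 || pgs_effect_r2 > 0.5)
    stop("pgs_effect_r2 must lie in [0, 0.5]")

  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, maf_range = maf_range, miss_rate = miss_rate,
    disorders = disorders, factor_loadings = factor_loadings,
    factor_corr = factor_corr, h2_per_disorder = h2_per_disorder,
    n_gwas_per_disorder = n_gwas_per_disorder, regions = regions,
    prop_prenatal = prop_prenatal, prop_postnatal = prop_postnatal,
    expr_effect = expr_effect, n_donors_pre = as.integer(n_donors_pre),
    n_donors_post = as.integer(n_donors_post),
    pheno_target_corr = pheno_target_corr,
    causal_partition = causal_partition, pgs_effect_r2 = pgs_effect_r2,
    n_sites = as.integer(n_sites), site_var_prop = site_var_prop,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "individuals,", x$n_snps, "SNPs,",
      x$n_genes, "genes,", length(x$disorders), "disorders\n")
  cat("  LD: blocks of", x$ld_block_size, "SNPs, rho =", x$ld_rho,
      "; MAF in [", x$maf_range[1], ",", x$maf_range[2], "]\n")
  cat("  causal partition:", x$causal_partition[1], "/",
      x$causal_partition[2], "; target R2 =", x$pgs_effect_r2, "\n")
  invisible(x)
}
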