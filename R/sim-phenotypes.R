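#' Clinical-range flag from a Total T-score
#'
#' The clinical cutoff is inclusive: a Total score exactly at the cutoff
#' counts as clinical-range.
#' @param total numeric Total-scale T-scores.
#' @param cutoff clinical cutoff (default 64).
#' @return logical vector.
#' @export
clinical_flag <- function(total, cutoff = 64) total >= cutoff

#' Simulate the 12-scale phenotype table from a panel and truth record
#'
#' Builds the true partitioned genetic liability as the standardized sum
#' over causal-partition SNPs of their factor-level effects times the
#' standardized dosages (the truth record's `causal_snps`, i.e. SNPs
#' annotated to genes of the causal timing class in the causal region).
#' The 12 scales are generated so their population correlation equals
#' the configured target matrix while a `pgs_effect_r2` share of the
#' Total scale's variance is explained by the liability: scale j loads
#' sqrt(r2) * C[j, Total] on the liability and the residual covariance
#' is C minus that rank-one part. Site random intercepts, small age and
#' sex effects, and principal components from the panel are added, all
#' on a T-score-like scale (mean 50, SD 10); the clinical flag is
#' Total >= 64.
#'
#' @param config a [sim_config()].
#' @param panel a [genotype_panel()].
#' @param truth a `truth_record` carrying `factor_effects`, `snp_ids`
#'   and `causal_snps` (see [simulate_study()]).
#' @param n_pc_snps SNP subsample size for the PC computation (default
#'   1000; PCs carry no ancestry structure in this homogeneous cohort).
#' @return data.frame (class `phenotype_table`): sample_id, 12 scales,
#'   age, sex, site, PC1-PC5, clinical. The realized liability is
#'   attached as attribute `liability`.
#' @export
simulate_phenotypes <- function(config, panel, truth, n_pc_snps = 1000) {
  C <- config$pheno_target_corr
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("pheno_target_corr is not positive-semidefinite; ",
         "smooth it with smooth_to_pd() first")
  scales <- colnames(C) %||% c("anxdep", "withdep", "somatic", "social",
                               "thought", "attention", "rulebreak",
                               "aggressive", "internalizing",
                               "externalizing", "total", "psychosis")
  colnames(C) <- rownames(C) <- scales
  if (!"total" %in% scales) stop("pheno_target_corr must include a total scale")
  set.seed(config$seed + 4L)
  n <- length(panel$sample_ids)

  causal <- intersect(truth$causal_snps %||% character(0), truth$snp_ids)
  r2 <- config$pgs_effect_r2
  if (length(causal) && r2 > 0) {
    idx <- match(causal, truth$snp_ids)
    Xs <- standardize_dosage(panel$dosage[, idx, drop = FALSE])
    u <- truth$factor_effects[idx, "NDV"]
    g <- as.vector(Xs %*% u)
    g <- (g - mean(g)) / stats::sd(g)
  } else {
    g <- rep(0, n)
    r2 <- 0
  }

  age <- stats::runif(n, 9, 11)
  sex <- stats::rbinom(n, 1, 0.5)
  site <- sample(seq_len(config$n_sites), n, replace = TRUE)
  site_eff <- stats::rnorm(config$n_sites, 0, sqrt(config$site_var_prop))
  # small covariate effects shared across scales
  covar <- 0.05 * (age - 10) + 0.10 * (sex - 0.5) + site_eff[site]

  # residual structure: target C minus the rank-one genetic part and the
  # shared covariate covariance, so the total correlation matches C
  a <- sqrt(r2) * C[, "total"]
  v_c <- stats::var(covar)
  Sig_e <- C - tcrossprod(a) - v_c
  Sig_e <- smooth_to_pd(Sig_e, 1e-12)$mat
  Z <- matrix(stats::rnorm(n * ncol(C)), n) %*% chol(Sig_e)
  Y <- outer(g, a) + covar + Z

  T_scores <- 50 + 10 * Y
  colnames(T_scores) <- scales

  n_pc_snps <- min(n_pc_snps, ncol(panel$dosage))
  pcs_idx <- sort(sample.int(ncol(panel$dosage), n_pc_snps))
  Xp <- standardize_dosage(panel$dosage[, pcs_idx, drop = FALSE])
  pc <- stats::prcomp(Xp, center = FALSE, scale. = FALSE, rank. = 5)
  PC <- pc$x[, 1:5, drop = FALSE]
  colnames(PC) <- paste0("PC", 1:5)

  out <- data.frame(sample_id = panel$sample_ids, T_scores, age = age,
                    sex = sex, site = factor(site), PC,
                    clinical = clinical_flag(T_scores[, "total"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "liability") <- g
  out
}

#' Write a phenotype table as TSV
#' @param pheno a `phenotype_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
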