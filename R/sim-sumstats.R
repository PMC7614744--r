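#' Per-block empirical LD (correlation) matrices of a panel
#' @keywords internal
panel_block_cor <- function(panel, config = NULL) {
  block <- attr(panel, "ld_blocks")
  if (is.null(block)) {
    b <- config$ld_block_size %||% ncol(panel$dosage)
    block <- rep(seq_len(ceiling(ncol(panel$dosage) / b)),
                 each = b)[seq_len(ncol(panel$dosage))]
  }
  Xs <- standardize_dosage(panel$dosage)
  n <- nrow(Xs)
  lapply(split(seq_along(block), block), function(idx) {
    R <- crossprod(Xs[, idx, drop = FALSE]) / (n - 1L)
    diag(R) <- 1
    R
  })
}

#' Simulate GWAS summary statistics for eight disorders with a planted
#' three-factor genetic architecture
#'
#' True standardized per-SNP effects follow the factor model
#' u_j = Lambda g + e, where the factor effects g are drawn from the
#' planted factor correlation and uniquenesses top the per-disorder
#' genetic variance up to 1; effects are scaled so each disorder's total
#' SNP heritability equals `h2_per_disorder`. Observed z-scores are
#' generated analytically: the marginal (LD-smeared) effect is R u per
#' block using the panel's empirical dosage correlations, and noise is
#' drawn with the same correlation, so E[chi2_j] = 1 + n h2 l_j / M holds
#' exactly with respect to the panel LD scores.
#'
#' @param config a [sim_config()].
#' @param panel a [genotype_panel()] (typically from [simulate_genotypes()]).
#' @return list with `sumstats` (named list of [sumstats()] objects, one
#'   per disorder) and `truth` (a `truth_record`: per-SNP joint effects,
#'   factor-level effects, and the planted covariance).
#' @export
simulate_multitrait_sumstats <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  L <- config$factor_loadings
  Phi <- config$factor_corr
  k <- length(config$disorders)
  if (nrow(L) != k) stop("factor_loadings must have one row per disorder")
  commun <- diag(L %*% Phi %*% t(L))
  if (any(commun > 1))
    stop("factor_loadings imply per-disorder genetic variance > 1")
  psi <- 1 - commun
  m <- nrow(panel$variants)
  h2 <- rep(config$h2_per_disorder, length.out = k)
  n_gwas <- rep(config$n_gwas_per_disorder, length.out = k)

  set.seed(config$seed + 1L)
  # factor-level and unique standardized effects (unit total variance per
  # disorder before h2/M scaling)
  G <- matrix(stats::rnorm(m * ncol(L)), m) %*% chol(Phi)
  E <- matrix(stats::rnorm(m * k), m) %*% diag(sqrt(psi), k)
  U <- G %*% t(L) + E                       # m x k, unit variance columns
  B <- sweep(U, 2, sqrt(h2 / m), "*")       # joint standardized effects

  # analytic GWAS: marginal effects are LD-smeared through the panel
  # correlations and sampling noise carries the same LD correlation, as
  # real GWAS z-scores do; either way E[chi2_j] = 1 + n h2 l_j / M holds
  # exactly with respect to panel LD
  blocks <- panel_block_cor(panel, config)
  freq <- allele_freq(panel)
  Z <- matrix(stats::rnorm(m * k), m, k)
  i0 <- 0L
  for (R in blocks) {
    nb <- nrow(R)
    idx <- i0 + seq_len(nb)
    smear <- R %*% B[idx, , drop = FALSE]
    noise <- if (nb > 1) {
      Ch <- chol(smooth_to_pd(R, 1e-8)$mat)
      t(Ch) %*% Z[idx, , drop = FALSE]
    } else Z[idx, , drop = FALSE]
    Z[idx, ] <- sweep(smear, 2, sqrt(n_gwas), "*") + noise
    i0 <- i0 + nb
  }

  ss <- vector("list", k)
  names(ss) <- config$disorders
  for (j in seq_len(k)) {
    se <- 1 / sqrt(n_gwas[j] * 2 * freq * (1 - freq))
    ss[[j]] <- sumstats(data.frame(
      chrom = panel$variants$chrom, pos = panel$variants$pos,
      id = panel$variants$id, a1 = panel$variants$a1, a2 = panel$variants$a2,
      beta = Z[, j] * se, se = se,
      p = pmax(2 * stats::pnorm(-abs(Z[, j])), 1e-300),
      n = n_gwas[j], info = rep(1, m), freq = freq,
      stringsAsFactors = FALSE))
  }

  truth <- structure(list(
    snp_effects = B,                       # m x k joint standardized effects
    factor_effects = sweep(G, 1, 0, "+"),  # m x 3, unit-variance scale
    disorders = config$disorders,
    factors = colnames(L),
    h2 = h2, n_gwas = n_gwas,
    genetic_cov = diag(sqrt(h2), k) %*% (L %*% Phi %*% t(L) + diag(psi, k)) %*%
      diag(sqrt(h2), k),
    snp_ids = panel$variants$id
  ), class = "truth_record")
  dimnames(truth$genetic_cov) <- list(config$disorders, config$disorders)

  list(sumstats = ss, truth = truth)
}
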