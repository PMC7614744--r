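#' Per-SNP common-factor GWAS from indicator summary statistics
#'
#' For each latent factor of the confirmatory model, each SNP's
#' standardized effects on the factor's indicators (beta_std = z /
#' sqrt(n * 2p(1-p)), with p the reference allele frequency) are treated
#' as the SNP-indicator genetic covariances that augment S, and the
#' SNP -> factor path is solved conditional on the measurement model
#' (loadings and residual variances fixed at the SNP-free CFA solution)
#' by weighted least squares, weighting each indicator covariance by its
#' inverse sampling variance. SNPs are processed independently; a SNP
#' absent from any indicator of a factor is emitted as missing for that
#' factor and counted.
#'
#' @param S genetic covariance matrix (from [ldsc_regression()]).
#' @param V sampling covariance of vech(S).
#' @param model_spec a [cfa_spec()]; default [default_cfa_spec()].
#' @param ss_list named list of indicator [sumstats()] (names must cover
#'   the model's indicators).
#' @param ref_freq data.frame with columns id, freq giving reference
#'   allele frequencies (effect-allele), e.g. from the LD panel.
#' @return named list of [sumstats()] objects, one per factor, with
#'   effective n = 1 / (se^2 * 2p(1-p)); attribute `n_missing` counts
#'   SNPs skipped per factor.
#' @export
common_factor_gwas <- function(S, V, model_spec = default_cfa_spec(),
                               ss_list, ref_freq) {
  fit <- cfa_wls(S, V, model_spec)
  lay <- fit$layout
  edges <- lay$edges
  loadings <- fit$estimates$estimate[seq_len(nrow(edges))]

  ref <- ss_list[[1]][, c("id", "a1", "a2")]
  aligned <- lapply(ss_list, function(s) align_to_reference(s, ref,
                                                            drop_ambiguous = FALSE)$ss)
  out <- list()
  n_missing <- integer(0)
  for (f in seq_along(model_spec$factors)) {
    fname <- names(model_spec$factors)[f]
    ind <- model_spec$factors[[f]]
    miss <- setdiff(ind, names(aligned))
    if (length(miss)) stop("no summary statistics for indicators: ",
                           paste(miss, collapse = ", "))
    lam_f <- loadings[edges$factor == f]
    names(lam_f) <- lay$traits[edges$trait[edges$factor == f]]
    lam_f <- lam_f[ind]

    ids <- Reduce(intersect, lapply(aligned[ind], function(s) s$id))
    ids <- intersect(ids, ref_freq$id)
    base <- aligned[[ind[1]]]
    n_missing[fname] <- length(unique(unlist(lapply(aligned[ind],
                                                    function(s) s$id)))) -
      length(ids)
    base <- base[match(ids, base$id), , drop = FALSE]
    p <- ref_freq$freq[match(ids, ref_freq$id)]
    var_snp <- 2 * p * (1 - p)

    m <- length(ids)
    num <- numeric(m); den <- numeric(m)
    for (j in seq_along(ind)) {
      sj <- aligned[[ind[j]]]
      sj <- sj[match(ids, sj$id), , drop = FALSE]
      z <- sj$beta / sj$se
      b_std <- z / sqrt(sj$n * var_snp)       # standardized SNP effect
      var_b <- 1 / (sj$n * var_snp)
      cj <- b_std * var_snp                    # SNP-indicator covariance
      var_c <- var_b * var_snp^2
      w <- 1 / var_c
      num <- num + w * lam_f[j] * cj
      den <- den + w * lam_f[j]^2
    }
    est <- num / (var_snp * den)
    se <- 1 / sqrt(var_snp^2 * den)
    z <- est / se
    out[[fname]] <- sumstats(data.frame(
      chrom = base$chrom, pos = base$pos, id = base$id,
      a1 = base$a1, a2 = base$a2,
      beta = est, se = se,
      p = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
      n = 1 / (se^2 * var_snp),
      freq = p, stringsAsFactors = FALSE))
  }
  attr(out, "n_missing") <- n_missing
  attr(out, "cfa_fit") <- fit
  out
}
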