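#' Gene-based association by the SNP-wise mean model
#'
#' The gene statistic is the mean chi-square (z^2) of the gene's
#' annotated SNPs. Under the null, k times the statistic is distributed
#' as the eigenvalue-weighted mixture sum(lambda_i chi2_1) where the
#' lambda_i are eigenvalues of the SNPs' dosage-correlation matrix in
#' the LD reference panel (ridge-regularised before decomposition). The
#' p-value uses a moment-matched (Satterthwaite) gamma approximation to
#' the mixture; `method = "montecarlo"` draws from the mixture instead.
#' Benjamini-Hochberg q-values are appended across genes.
#'
#' @param factor_ss a [sumstats()] object (e.g. one factor's GWAS).
#' @param annot a `snp_annotation` from [annotate_snps_to_genes()].
#' @param ld_panel reference [genotype_panel()] providing LD.
#' @param ridge diagonal ridge added to the correlation matrix (1e-6).
#' @param method "satterthwaite" (default) or "montecarlo".
#' @param mc_draws Monte Carlo draws when `method = "montecarlo"`.
#' @return data.frame (class `gene_assoc`): gene_id, n_snps, mean_chi2,
#'   p, q. Genes with no scoreable SNP are omitted with a warning.
#' @export
gene_snpwise_mean_test <- function(factor_ss, annot, ld_panel,
                                   ridge = 1e-6,
                                   method = c("satterthwaite", "montecarlo"),
                                   mc_draws = 1e5) {
  method <- match.arg(method)
  z2 <- (factor_ss$beta / factor_ss$se)^2
  names(z2) <- factor_ss$id
  Xs <- standardize_dosage(ld_panel$dosage)
  colnames(Xs) <- ld_panel$variants$id
  n <- nrow(Xs)

  genes <- unique(annot$map$gene_id)
  by_gene <- split(annot$map$snp_id, annot$map$gene_id)
  out <- vector("list", length(genes))
  n_empty <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    snps <- intersect(unique(by_gene[[g]]),
                      intersect(factor_ss$id, ld_panel$variants$id))
    k <- length(snps)
    if (k == 0) { n_empty <- n_empty + 1L; next }
    Tstat <- mean(z2[snps])
    R <- crossprod(Xs[, snps, drop = FALSE]) / (n - 1L)
    diag(R) <- diag(R) + ridge
    lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    # gamma moment match: mean sum(lam), var 2 sum(lam^2)
    sl <- sum(lam); sl2 <- sum(lam^2)
    if (method == "satterthwaite") {
      scale_g <- 2 * sl2 / sl
      shape_g <- sl^2 / (2 * sl2)
      p <- stats::pgamma(k * Tstat, shape = shape_g, scale = scale_g,
                         lower.tail = FALSE)
    } else {
      draws <- colSums(lam * matrix(stats::rchisq(length(lam) * mc_draws, 1),
                                    length(lam)))
      p <- (sum(draws >= k * Tstat) + 1) / (mc_draws + 1)
    }
    out[[gi]] <- data.frame(gene_id = g, n_snps = k, mean_chi2 = Tstat,
                            p = max(p, 1e-300), stringsAsFactors = FALSE)
  }
  if (n_empty > 0)
    warning(n_empty, " genes had no scoreable SNPs and were omitted")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop("no genes with scoreable SNPs")
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  class(res) <- c("gene_assoc", "data.frame")
  res
}

#' Gene-property regression of association on tissue expression
#'
#' Converts gene association p-values to z-scores (probit of 1 - p) and,
#' for each tissue, regresses gene z on that tissue's log expression,
#' covarying the average log expression across tissues, log gene length
#' and log SNP count. The reported p is one-sided for a positive
#' tissue-specificity coefficient; the Bonferroni threshold
#' 0.05 / n_tissues is attached as an attribute.
#'
#' @param gene_assoc a `gene_assoc` data.frame.
#' @param tissue_expr genes x tissues expression matrix (rownames gene
#'   ids); log2(x + 1)-transformed internally when `log_transform`.
#' @param gene_map a `gene_map` providing gene lengths.
#' @param log_transform log-transform expression first (default TRUE).
#' @return data.frame: tissue, beta, se, t, p_one_sided; attribute
#'   `bonferroni` gives the corrected threshold. Constant-expression
#'   tissues are skipped with a warning.
#' @export
gene_property_tissue_regression <- function(gene_assoc, tissue_expr,
                                            gene_map, log_transform = TRUE) {
  common <- intersect(gene_assoc$gene_id, rownames(tissue_expr))
  ga <- gene_assoc[match(common, gene_assoc$gene_id), , drop = FALSE]
  E <- tissue_expr[common, , drop = FALSE]
  if (log_transform) E <- log2(E + 1)
  z <- stats::qnorm(pmin(pmax(1 - ga$p, 1e-15), 1 - 1e-15))
  len <- gene_map$end - gene_map$start + 1
  loglen <- log(len[match(common, gene_map$gene_id)])
  logn <- log(ga$n_snps)
  avg <- rowMeans(E)
  out <- list()
  for (t in colnames(E)) {
    x <- E[, t]
    if (stats::sd(x) == 0) {
      warning("tissue ", t, " has constant expression; skipped")
      next
    }
    fit <- stats::lm(z ~ x + avg + loglen + logn)
    sm <- summary(fit)$coefficients
    tt <- sm["x", "t value"]
    out[[t]] <- data.frame(tissue = t, beta = sm["x", "Estimate"],
                           se = sm["x", "Std. Error"], t = tt,
                           p_one_sided = stats::pt(tt, fit$df.residual,
                                                   lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bonferroni") <- 0.05 / nrow(res)
  res
}

#' Top genes by ascending association p-value
#'
#' Selects the most significant fraction of genes (ties broken by id),
#' the selection used for downstream gene-set exploration; the top-5%
#' set size is ceil(0.05 * n_genes).
#' @param gene_assoc a `gene_assoc` data.frame.
#' @param top_frac fraction selected (default 0.05).
#' @return character vector of gene ids.
#' @export
top_genes <- function(gene_assoc, top_frac = 0.05) {
  n <- ceiling(top_frac * nrow(gene_assoc))
  ord <- order(gene_assoc$p, gene_assoc$gene_id)
  gene_assoc$gene_id[ord][seq_len(n)]
}
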