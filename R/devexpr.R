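#' Set-level pre/postnatal differential expression mixed model
#'
#' Fits expression ~ prenatal + (1 | gene) + (1 | donor) by REML on the
#' samples of one region, for a set of genes. The developmental window
#' is coded postnatal = 0, prenatal = 1, so a positive estimate means
#' higher prenatal expression. Expression is log2(x + 1)-transformed by
#' default. Inference on the prenatal term is a Wald z test. If the fit
#' is singular, the zero-variance random component(s) are dropped and
#' the model refit (down to plain least squares when both vanish).
#'
#' @param atlas an `expression_atlas`.
#' @param region one region label present in the atlas.
#' @param gene_set non-empty character vector of gene ids.
#' @param log_transform log2(x + 1) before modelling (default TRUE).
#' @return list: estimate (prenatal minus postnatal), se, z, p, n_genes,
#'   n_samples, dropped (names of random components removed).
#' @export
set_prepost_mixed_model <- function(atlas, region, gene_set,
                                    log_transform = TRUE) {
  if (!length(gene_set)) stop("gene_set is empty")
  if (!region %in% atlas$samples$region)
    stop("region ", region, " not present in atlas")
  gene_set <- intersect(gene_set, rownames(atlas$expr))
  if (!length(gene_set)) stop("no gene_set members found in atlas")
  sel <- atlas$samples$region == region
  E <- atlas$expr[gene_set, sel, drop = FALSE]
  if (log_transform) E <- log2(E + 1)
  meta <- atlas$samples[sel, ]
  d <- data.frame(
    expr = as.vector(E),
    gene = rep(gene_set, times = ncol(E)),
    donor = rep(meta$donor_id, each = nrow(E)),
    prenatal = rep(as.numeric(meta$prenatal), each = nrow(E)))

  dropped <- character(0)
  forms <- list(
    expr ~ prenatal + (1 | gene) + (1 | donor),
    expr ~ prenatal + (1 | gene),
    expr ~ prenatal + (1 | donor))
  fit <- NULL
  used <- NULL
  for (fo in forms) {
    f <- suppressMessages(suppressWarnings(
      lme4::lmer(fo, data = d, REML = TRUE)))
    if (!lme4::isSingular(f, tol = 1e-6)) { fit <- f; used <- fo; break }
    if (is.null(fit)) { fit <- f; used <- fo }  # keep first as fallback
  }
  if (lme4::isSingular(fit, tol = 1e-6)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    dropped <- vc$grp[vc$vcov < 1e-10]
    lf <- stats::lm(expr ~ prenatal, data = d)
    est <- stats::coef(lf)[["prenatal"]]
    se <- summary(lf)$coefficients["prenatal", "Std. Error"]
  } else {
    if (!identical(deparse(used), deparse(forms[[1]])))
      dropped <- setdiff(c("gene", "donor"),
                         names(lme4::ranef(fit)))
    co <- summary(fit)$coefficients
    est <- co["prenatal", "Estimate"]
    se <- co["prenatal", "Std. Error"]
  }
  z <- est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       n_genes = length(gene_set), n_samples = sum(sel), dropped = dropped)
}

#' Classify genes as prenatal / postnatal / continuous in one region
#'
#' Per gene, donor-level replicate samples are averaged (one value per
#' donor) and a Welch two-sample t-test contrasts mean prenatal versus
#' postnatal expression (log2(x + 1) scale). Benjamini-Hochberg FDR is
#' applied across all genes tested in the region; genes with q below
#' `q_threshold` are classed prenatal (positive estimate, pre minus
#' post) or postnatal (negative estimate), all others continuous. Genes
#' with fewer than 2 donors per window are classed continuous and
#' flagged.
#'
#' @param atlas an `expression_atlas`.
#' @param region region label.
#' @param q_threshold FDR threshold (default 0.05).
#' @param log_transform log2(x + 1) first (default TRUE).
#' @return data.frame (class `gene_partition`): region, gene_id, class,
#'   estimate, p, q, flagged.
#' @export
classify_genes_prepost <- function(atlas, region, q_threshold = 0.05,
                                   log_transform = TRUE) {
  sel <- atlas$samples$region == region
  meta <- atlas$samples[sel, ]
  if (length(unique(meta$donor_id[meta$prenatal])) < 2 ||
      length(unique(meta$donor_id[!meta$prenatal])) < 2)
    stop("need >= 2 donors per developmental window in region ", region)
  E <- atlas$expr[, sel, drop = FALSE]
  if (log_transform) E <- log2(E + 1)
  # average replicates within donor
  donor_means <- t(apply(E, 1, function(y) {
    tapply(y, meta$donor_id, mean, na.rm = TRUE)
  }))
  donors <- colnames(donor_means)
  pre <- donors %in% meta$donor_id[meta$prenatal]

  ng <- nrow(E)
  est <- p <- rep(NA_real_, ng)
  flagged <- rep(FALSE, ng)
  for (g in seq_len(ng)) {
    a <- donor_means[g, pre]
    b <- donor_means[g, !pre]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) { flagged[g] <- TRUE; next }
    est[g] <- mean(a) - mean(b)
    if (stats::sd(c(a, b)) == 0) { p[g] <- 1; next }
    p[g] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }
  q <- rep(NA_real_, ng)
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  cls <- rep("continuous", ng)
  cls[ok & q < q_threshold & est > 0] <- "prenatal"
  cls[ok & q < q_threshold & est < 0] <- "postnatal"
  out <- data.frame(region = region, gene_id = rownames(E), class = cls,
                    estimate = est, p = p, q = q, flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_partition", "data.frame")
  out
}

#' Classify genes in every region of the atlas
#' @inheritParams classify_genes_prepost
#' @return row-bound `gene_partition` over all regions.
#' @export
classify_genes_all_regions <- function(atlas, q_threshold = 0.05,
                                       log_transform = TRUE) {
  out <- do.call(rbind, lapply(unique(atlas$samples$region), function(r)
    classify_genes_prepost(atlas, r, q_threshold, log_transform)))
  class(out) <- c("gene_partition", "data.frame")
  out
}

#' Write a gene partition table as TSV
#' @param partition a `gene_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
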