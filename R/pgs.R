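#' Greedy p-value-ordered LD clumping
#'
#' Sorts variants by ascending p (ties: position, then id) and accepts a
#' variant only if its squared dosage correlation with every previously
#' accepted variant within `window_kb` is at most `r2_max`. Variants
#' absent from the reference panel are dropped and counted.
#'
#' @param ss a [sumstats()] object, allele-aligned to the panel.
#' @param ld_panel reference [genotype_panel()].
#' @param r2_max clumping r2 ceiling (default 0.1).
#' @param window_kb clumping window in kb (default 250).
#' @return the index-SNP subset of `ss` (original row order); attribute
#'   `n_dropped_missing` counts SNPs absent from the panel.
#' @export
clump <- function(ss, ld_panel, r2_max = 0.1, window_kb = 250) {
  inpanel <- ss$id %in% ld_panel$variants$id
  n_missing <- sum(!inpanel)
  s <- ss[inpanel, , drop = FALSE]
  if (!nrow(s)) {
    out <- s
    attr(out, "n_dropped_missing") <- n_missing
    return(out)
  }
  Xs <- standardize_dosage(ld_panel$dosage)
  colnames(Xs) <- ld_panel$variants$id
  n <- nrow(Xs)
  w <- window_kb * 1000

  ord <- order(s$p, s$pos, s$id)
  accept <- logical(nrow(s))
  for (ii in ord) {
    cand_chr <- s$chrom[ii]
    cand_pos <- s$pos[ii]
    near <- which(accept & s$chrom == cand_chr & abs(s$pos - cand_pos) <= w)
    ok <- TRUE
    if (length(near)) {
      r <- crossprod(Xs[, s$id[ii]], Xs[, s$id[near], drop = FALSE]) / (n - 1L)
      ok <- all(r^2 <= r2_max)
    }
    accept[ii] <- ok
  }
  out <- s[accept, , drop = FALSE]
  attr(out, "n_dropped_missing") <- n_missing
  out
}

#' Clumping-and-thresholding polygenic scores
#'
#' For each p-value inclusion threshold Pt, the score of an individual
#' is the sum over variants with p <= Pt of beta times the dosage of the
#' effect allele. Alleles are aligned to the panel (swapped orientation
#' counts the complementary dosage 2 - d; mismatched variants are
#' dropped); missing dosages are imputed as twice the panel allele
#' frequency.
#'
#' @param panel target [genotype_panel()].
#' @param ss (clumped) [sumstats()].
#' @param pt_grid p-value thresholds (default 0.001, 0.01, 0.05, 0.1,
#'   0.5, 1.0; 1.0 is the primary threshold downstream).
#' @return a `score_matrix`: individuals x thresholds matrix with a
#'   `meta` attribute describing each column.
#' @export
score_pgs <- function(panel, ss, pt_grid = c(0.001, 0.01, 0.05, 0.1, 0.5, 1.0)) {
  al <- align_to_reference(ss, panel$variants, drop_ambiguous = FALSE)
  s <- al$ss
  # swapped variants count the other allele: beta * (2 - d) equals the
  # flipped-beta dosage product plus a per-variant constant 2 * beta
  offset_beta <- -s$beta * al$swapped
  D <- panel$dosage[, s$id, drop = FALSE]
  if (anyNA(D)) {
    f <- allele_freq(panel)[match(s$id, panel$variants$id)]
    imp <- matrix(rep(2 * f, each = nrow(D)), nrow(D))
    D[is.na(D)] <- imp[is.na(D)]
  }
  scores <- matrix(0, nrow(panel$dosage), length(pt_grid),
                   dimnames = list(panel$sample_ids,
                                   paste0("Pt_", pt_grid)))
  for (i in seq_along(pt_grid)) {
    use <- s$p <= pt_grid[i]
    if (!any(use)) {
      warning("no SNPs at Pt = ", pt_grid[i], "; zero column emitted")
      next
    }
    scores[, i] <- D[, use, drop = FALSE] %*% s$beta[use] +
      2 * sum(offset_beta[use])
  }
  structure(scores, meta = data.frame(column = colnames(scores),
                                      pt = pt_grid,
                                      n_snps = vapply(pt_grid, function(pt)
                                        sum(s$p <= pt), numeric(1))),
            class = c("score_matrix", class(scores)))
}

#' Z-standardize score columns and assign quintiles
#'
#' Standardizes each column to mean 0, SD 1 and assigns quintiles from
#' the empirical 20/40/60/80 percentiles; ties are resolved by stable
#' sample order. Zero-variance columns are left unstandardized and
#' flagged (no quintiles).
#'
#' @param scores matrix of raw scores (individuals x columns).
#' @return list: `z` (standardized matrix), `quintile` (integer matrix,
#'   1 = bottom, 5 = top), `flagged` (zero-variance column names).
#' @export
standardize_and_quintile <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 5) stop("need >= 5 individuals for quintiles")
  z <- scores
  qm <- matrix(NA_integer_, n, ncol(scores), dimnames = dimnames(scores))
  flagged <- character(0)
  for (j in seq_len(ncol(scores))) {
    s <- stats::sd(scores[, j])
    if (s == 0 || !is.finite(s)) {
      flagged <- c(flagged, colnames(scores)[j] %||% as.character(j))
      next
    }
    z[, j] <- (scores[, j] - mean(scores[, j])) / s
    rk <- rank(scores[, j], ties.method = "first")
    qm[, j] <- as.integer(floor((rk - 1) * 5 / n) + 1)
  }
  list(z = z, quintile = qm, flagged = flagged)
}

#' Developmental-timing-partitioned polygenic scores
#'
#' For each of the 6 regions x 3 timing classes, takes the SNPs
#' annotated to at least one gene of that class in that region, clumps
#' the subset and scores it at Pt = 1.0, yielding exactly 18 score
#' columns named `<REGION>_<class>`. A SNP mapping to genes of several
#' classes contributes to each matching partition. Empty partitions give
#' a zero column with a warning.
#'
#' @param factor_ss factor-level [sumstats()] (e.g. the NDV factor).
#' @param annot a `snp_annotation`.
#' @param partitions a `gene_partition` covering the regions.
#' @param panel target [genotype_panel()] (also the LD reference for
#'   clumping).
#' @param r2_max,window_kb clumping parameters.
#' @param pt p-value threshold (default 1.0).
#' @param reclump clump each partition's subset independently (default
#'   TRUE); FALSE reuses one clump of the full summary statistics.
#' @param regions,classes partitions to compute (defaults: all 6 regions
#'   x 3 classes).
#' @return a `score_matrix` with one column per (region, class) and a
#'   `meta` attribute (column, region, class, n_snps).
#' @export
partition_sumstats_and_score <- function(factor_ss, annot, partitions, panel,
                                         r2_max = 0.1, window_kb = 250,
                                         pt = 1.0, reclump = TRUE,
                                         regions = NULL, classes = NULL) {
  regions <- regions %||% unique(partitions$region)
  classes <- classes %||% c("prenatal", "postnatal", "continuous")
  parent <- if (!reclump) clump(factor_ss, panel, r2_max, window_kb) else NULL

  cols <- list()
  meta <- list()
  for (r in regions) {
    pr <- partitions[partitions$region == r, , drop = FALSE]
    for (cl in classes) {
      nm <- paste0(r, "_", cl)
      genes <- pr$gene_id[pr$class == cl]
      snps <- snps_of_gene(annot, genes)
      base <- if (reclump) factor_ss else parent
      sub <- base[base$id %in% snps & base$p <= pt, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning("empty partition ", nm, "; zero column emitted")
        cols[[nm]] <- rep(0, length(panel$sample_ids))
        meta[[nm]] <- data.frame(column = nm, region = r, class = cl,
                                 n_snps = 0L)
        next
      }
      idx <- if (reclump) clump(sub, panel, r2_max, window_kb) else sub
      sc <- score_pgs(panel, idx, pt_grid = pt)
      cols[[nm]] <- sc[, 1]
      meta[[nm]] <- data.frame(column = nm, region = r, class = cl,
                               n_snps = attr(sc, "meta")$n_snps[1])
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- panel$sample_ids
  structure(M, meta = do.call(rbind, meta),
            class = c("score_matrix", class(M)))
}
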