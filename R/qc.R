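#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the observed
#' allele counts (the PLINK-style exact test). The two-sided p-value sums
#' the probabilities of all heterozygote configurations no more probable
#' than the observed one.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)  # monomorphic: single configuration
  hs <- seq(rare %% 2L, rare, by = 2L)
  # P(het = h | allele counts) up to a constant, in log space
  logp <- -lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

panel_geno_counts <- function(panel) {
  D <- panel$dosage
  cbind(AA = colSums(D == 2, na.rm = TRUE),
        Aa = colSums(D == 1, na.rm = TRUE),
        aa = colSums(D == 0, na.rm = TRUE))
}

#' Variant-level quality-control filter
#'
#' Retains variants with minor allele frequency >= `maf_min`, missingness
#' <= `miss_max` and (for genotype panels) HWE exact p >= `hwe_min`, or
#' (for summary statistics) imputation INFO >= `info_min`. The report
#' attributes each removal to the first failing criterion in the order
#' MAF, missingness, HWE/INFO.
#'
#' @param x a [genotype_panel()] or [sumstats()] object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum per-variant missingness (default 0.05).
#' @param hwe_min minimum HWE exact p (panels; default 1e-5).
#' @param info_min minimum INFO score (sumstats; default 0.9).
#' @return list with `object` (filtered) and `report` (criterion counts).
#' @export
variant_qc_filter <- function(x, maf_min = 0.01, miss_max = 0.05,
                              hwe_min = 1e-5, info_min = 0.9) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            hwe_min >= 0, hwe_min <= 1, info_min >= 0, info_min <= 1)
  UseMethod("variant_qc_filter")
}

#' @export
variant_qc_filter.genotype_panel <- function(x, maf_min = 0.01,
                                             miss_max = 0.05, hwe_min = 1e-5,
                                             info_min = 0.9) {
  f <- allele_freq(x)
  maf <- pmin(f, 1 - f)
  miss <- colMeans(is.na(x$dosage))
  gc <- panel_geno_counts(x)
  hwe <- vapply(seq_len(nrow(gc)),
                function(j) hwe_exact_test(gc[j, 1], gc[j, 2], gc[j, 3]),
                numeric(1))
  fail_maf <- maf < maf_min | is.na(maf)
  fail_miss <- !fail_maf & miss > miss_max
  fail_hwe <- !fail_maf & !fail_miss & hwe < hwe_min
  keep <- !(fail_maf | fail_miss | fail_hwe)
  report <- data.frame(criterion = c("maf", "missingness", "hwe"),
                       n_removed = c(sum(fail_maf), sum(fail_miss),
                                     sum(fail_hwe)))
  list(object = subset_panel(x, variants = which(keep)), report = report)
}

#' @export
variant_qc_filter.sumstats <- function(x, maf_min = 0.01, miss_max = 0.05,
                                       hwe_min = 1e-5, info_min = 0.9) {
  maf <- if (!is.null(x$freq)) pmin(x$freq, 1 - x$freq) else rep(NA_real_, nrow(x))
  info <- x$info %||% rep(NA_real_, nrow(x))
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_info <- !fail_maf & !is.na(info) & info < info_min
  keep <- !(fail_maf | fail_info)
  report <- data.frame(criterion = c("maf", "info"),
                       n_removed = c(sum(fail_maf), sum(fail_info)))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(object = out, report = report)
}

#' Greedy LD pruning within sliding windows
#'
#' Scans variants left to right per chromosome; for any pair closer than
#' `window_kb` whose squared dosage correlation exceeds `r2_max`, the
#' later-position variant is removed (same position: the lower-MAF one).
#' With a step no larger than the window, PLINK's stepped sliding windows
#' compare exactly the pairs within `window_kb` of each other, which is
#' how the window is applied here. Correlations use pairwise-complete
#' observations.
#'
#' @param panel a [genotype_panel()].
#' @param window_kb window size in kb (default 50).
#' @param step_kb step size in kb (default 5; retained for interface
#'   compatibility, see above).
#' @param r2_max maximum retained squared correlation (default 0.5).
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(panel, window_kb = 50, step_kb = 5, r2_max = 0.5) {
  v <- panel$variants
  D <- panel$dosage
  f <- allele_freq(panel)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, nrow(v))
  has_na <- anyNA(D)
  Xs <- if (!has_na) standardize_dosage(D) else NULL
  n <- nrow(D)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    for (a in seq_along(idx)) {
      j <- idx[a]
      if (!keep[j]) next
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= window_kb * 1000) {
        k <- idx[b]
        if (keep[k]) {
          r <- if (!has_na) sum(Xs[, j] * Xs[, k]) / (n - 1L)
               else stats::cor(D[, j], D[, k], use = "pairwise.complete.obs")
          if (!is.na(r) && r^2 > r2_max) {
            if (pos[b] > pos[a]) keep[k] <- FALSE
            else if (maf[k] <= maf[j]) keep[k] <- FALSE
            else { keep[j] <- FALSE; break }
          }
        }
        b <- b + 1L
      }
    }
  }
  v$id[keep]
}

#' Ancestry outlier filter from principal components
#'
#' Computes principal components of the standardized dosage matrix
#' (missing entries mean-imputed) and removes samples falling more than
#' `sd_limit` standard deviations from the mean on any of the first
#' `n_pcs` components. A single pass is made (no recomputation loop).
#'
#' @param panel a [genotype_panel()] (LD-pruned upstream by convention).
#' @param n_pcs number of components inspected (default 4).
#' @param sd_limit outlier threshold in SD units (default 4).
#' @return list with `sample_ids` retained, `pcs` (all samples x n_pcs)
#'   and `removed`.
#' @export
pca_ancestry_filter <- function(panel, n_pcs = 4, sd_limit = 4) {
  n <- length(panel$sample_ids)
  m <- nrow(panel$variants)
  if (n_pcs > min(n, m)) stop("n_pcs exceeds min(samples, variants)")
  Xs <- standardize_dosage(panel$dosage)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  zs <- scale(scores)
  out <- apply(abs(zs) > sd_limit, 1, any)
  rownames(scores) <- panel$sample_ids
  list(sample_ids = panel$sample_ids[!out],
       pcs = scores,
       removed = panel$sample_ids[out])
}

#' Pairwise IBD estimation and relatedness filtering
#'
#' Method-of-moments PLINK-style estimation: observed identity-by-state
#' counts per pair are converted to P(IBD = 0, 1, 2) using their expected
#' values under the sample allele frequencies, giving pi-hat = P(IBD=2) +
#' P(IBD=1)/2. Pairs with pi-hat above `pi_hat_max` are resolved greedily
#' (worst pair first) by removing the member with higher missingness
#' (tie: the later sample id) until no offending pair remains.
#'
#' @param panel a [genotype_panel()] with >= 2 samples.
#' @param pi_hat_max relatedness ceiling (default 0.125).
#' @return list with `sample_ids` retained, `removed`, and `pi_hat`
#'   (data.frame of all pairs).
#' @export
ibd_filter <- function(panel, pi_hat_max = 0.125) {
  n <- length(panel$sample_ids)
  if (n < 2) stop("ibd_filter needs >= 2 samples")
  D <- panel$dosage
  p <- allele_freq(panel)
  q <- 1 - p
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_z1 <- 2 * p * q
  e2_z1 <- p^2 + q^2

  pairs <- utils::combn(n, 2)
  pi_hat <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    d <- abs(D[i, ] - D[j, ])
    ok <- !is.na(d)
    N0 <- sum(d[ok] == 2); N2 <- sum(d[ok] == 0); N1 <- sum(d[ok] == 1)
    s0 <- sum(e0_z0[ok]); s1 <- sum(e1_z0[ok]); s2 <- sum(e2_z0[ok])
    t1 <- sum(e1_z1[ok]); t2 <- sum(e2_z1[ok]); m_ok <- sum(ok)
    z0 <- if (s0 > 0) N0 / s0 else 0
    z1 <- if (t1 > 0) (N1 - z0 * s1) / t1 else 0
    z2 <- (N2 - z0 * s2 - z1 * t2) / m_ok
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    pi_hat[c_i] <- z[3] + z[2] / 2
  }
  pair_df <- data.frame(id1 = panel$sample_ids[pairs[1, ]],
                        id2 = panel$sample_ids[pairs[2, ]],
                        pi_hat = pi_hat)
  miss <- rowMeans(is.na(D))
  names(miss) <- panel$sample_ids
  retained <- panel$sample_ids
  repeat {
    live <- pair_df$id1 %in% retained & pair_df$id2 %in% retained
    off <- pair_df[live & pair_df$pi_hat > pi_hat_max, , drop = FALSE]
    if (!nrow(off)) break
    worst <- off[which.max(off$pi_hat), ]
    m1 <- miss[[worst$id1]]; m2 <- miss[[worst$id2]]
    drop_id <- if (m1 > m2) worst$id1
               else if (m2 > m1) worst$id2
               else max(worst$id1, worst$id2)
    retained <- setdiff(retained, drop_id)
  }
  list(sample_ids = retained,
       removed = setdiff(panel$sample_ids, retained),
       pi_hat = pair_df)
}
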