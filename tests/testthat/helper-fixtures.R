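# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# tiny panel from an explicit dosage matrix (variants on one chromosome,
# 10 kb apart unless positions given)
toy_panel <- function(dosage, pos = NULL, a1 = NULL, a2 = NULL,
                      chrom = "1") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  pos <- pos %||% (seq_len(m) * 10000L)
  genotype_panel(
    sprintf("s%03d", seq_len(nrow(dosage))),
    data.frame(chrom = chrom, pos = as.integer(pos),
               id = sprintf("v%03d", seq_len(m)),
               a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m),
               stringsAsFactors = FALSE),
    dosage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sumstats from a z-score vector on a panel's variants
toy_sumstats <- function(panel, z, n = 10000) {
  f <- pmin(pmax(colMeans(panel$dosage, na.rm = TRUE) / 2, 0.01), 0.99)
  se <- 1 / sqrt(n * 2 * f * (1 - f))
  sumstats(data.frame(
    chrom = panel$variants$chrom, pos = panel$variants$pos,
    id = panel$variants$id, a1 = panel$variants$a1, a2 = panel$variants$a2,
    beta = z * se, se = se, p = pmax(2 * pnorm(-abs(z)), 1e-300),
    n = n, freq = f, stringsAsFactors = FALSE))
}

# 8 orthogonal dosage columns (Hadamard pattern: exact zero pairwise
# correlation), n = 8 individuals
hadamard_panel <- function(k = 4) {
  H <- matrix(1, 1, 1)
  while (ncol(H) < max(k + 1, 2)) H <- rbind(cbind(H, H), cbind(H, -H))
  D <- (H[, 2:(k + 1), drop = FALSE] + 1)  # columns in {0, 2}, mean 1
  toy_panel(D)
}

# independent step-up BH oracle (kept free of stats::p.adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# brute-force greedy clumping oracle on a correlation matrix
clump_oracle <- function(p, pos, R, r2_max, window) {
  ord <- order(p, pos)
  acc <- integer(0)
  for (i in ord) {
    near <- acc[abs(pos[acc] - pos[i]) <= window]
    if (all(R[i, near]^2 <= r2_max)) acc <- c(acc, i)
  }
  sort(acc)
}

# brute-force greedy pruning oracle (drop later SNP of offending pair)
prune_oracle <- function(pos, R, r2_max, window) {
  keep <- rep(TRUE, length(pos))
  for (j in seq_along(pos)) {
    if (!keep[j]) next
    for (k in seq_along(pos)) {
      if (k <= j || !keep[k]) next
      if (abs(pos[k] - pos[j]) <= window && R[j, k]^2 > r2_max)
        keep[k] <- FALSE
    }
  }
  which(keep)
}

# full-enumeration HWE exact oracle: multinomial probabilities of every
# genotype configuration with the observed allele counts
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-12)])
}
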