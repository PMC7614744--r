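#' Simulate an LD-blocked genotype panel in Hardy-Weinberg equilibrium
#'
#' Genotypes are built from two independent latent haplotypes per
#' individual. Within each LD block the latent Gaussian follows a
#' first-order autoregressive process with parameter `ld_rho`; blocks are
#' mutually independent. Each haplotype carries the counted allele when
#' its latent value exceeds the upper `maf` quantile, so the marginal
#' allele frequency is exact and genotypes are in HWE by construction.
#'
#' Positions are 1-based and strictly increasing on a single chromosome:
#' SNPs within a block are spaced 5 kb apart and consecutive blocks are
#' separated by a 500 kb gap, so LD never spans blocks even under wide
#' analysis windows.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()] with an `ld_blocks` attribute giving each
#'   variant's block index.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  if (n < 2) stop("n_individuals must be >= 2")
  if (m < 1) stop("n_snps must be >= 1")
  rho <- config$ld_rho
  if (rho < 0 || rho >= 1) stop("ld_rho must lie in [0, 1)")
  set.seed(config$seed)

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(1 - maf)

  b <- config$ld_block_size
  block <- rep(seq_len(ceiling(m / b)), each = b)[seq_len(m)]

  ar1_latent <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0) {
      sig <- sqrt(1 - rho^2)
      for (j in 2:m) {
        if (block[j] == block[j - 1L])
          Z[, j] <- rho * Z[, j - 1L] + sig * Z[, j]
      }
    }
    Z
  }
  H1 <- sweep(ar1_latent(), 2, thr, ">")
  H2 <- sweep(ar1_latent(), 2, thr, ">")
  D <- H1 + H2
  storage.mode(D) <- "double"

  if (config$miss_rate > 0) {
    nmiss <- round(config$miss_rate * length(D))
    D[sample.int(length(D), nmiss)] <- NA
  }

  # positions: 5 kb within-block spacing, 500 kb inter-block gaps; blocks
  # are spread over up to 22 chromosomes so coordinates stay in range
  nb <- max(block)
  n_chrom <- min(22L, nb)
  chrom_of_block <- sort(rep_len(seq_len(n_chrom), nb))
  chrom <- as.character(chrom_of_block[block])
  new_chrom <- c(TRUE, diff(chrom_of_block[block]) != 0)
  step <- ifelse(new_chrom, 0, ifelse(c(FALSE, diff(block) != 0), 500000, 5000))
  pos <- 10000 + stats::ave(step, chrom, FUN = cumsum)

  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pk <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]

  variants <- data.frame(
    chrom = chrom, pos = as.integer(pos),
    id = sprintf("snp%06d", seq_len(m)),
    a1 = pk[, 1], a2 = pk[, 2],
    stringsAsFactors = FALSE
  )
  panel <- genotype_panel(sprintf("ind%05d", seq_len(n)), variants, D)
  attr(panel, "ld_blocks") <- block
  attr(panel, "true_maf") <- maf
  panel
}

#' Reference panel design for LD-score regression calibration
#'
#' LDSC separates polygenicity (slope) from confounding (intercept) most
#' precisely when the LD-score distribution has two well-separated
#' strata: isolated variants (LD score 1) anchor the intercept, while
#' many small high-LD blocks carry the slope information with enough
#' independent LD units to keep the slope variance low. This constructor
#' concatenates the two strata (distinct chromosome labels), which is
#' the panel used for heritability-recovery calibration.
#'
#' @param n_individuals panel size (default 500).
#' @param n_iso number of isolated variants (default 4000).
#' @param n_block number of variants in LD blocks (default 16000).
#' @param block_size SNPs per LD block (default 10).
#' @param rho within-block latent AR(1) correlation (default 0.95).
#' @param seed integer seed.
#' @return a [genotype_panel()] with `ld_blocks` attribute.
#' @export
simulate_ldsc_calibration_panel <- function(n_individuals = 500,
                                            n_iso = 4000, n_block = 16000,
                                            block_size = 10, rho = 0.95,
                                            seed = 1L) {
  base <- function(n_snps, bs, r, maf, sd_) {
    cfg <- sim_config(n_individuals = n_individuals, n_snps = n_snps,
                      ld_block_size = bs, ld_rho = r, maf_range = maf,
                      seed = sd_, disorders = "T", h2_per_disorder = 0,
                      factor_loadings = matrix(1, 1, 1),
                      factor_corr = matrix(1, 1, 1))
    simulate_genotypes(cfg)
  }
  pA <- base(n_iso, 1L, 0, c(0.05, 0.5), seed)
  pB <- base(n_block, block_size, rho, c(0.2, 0.5), seed + 1L)
  vB <- pB$variants
  vB$chrom <- paste0("B", vB$chrom)
  vB$id <- paste0("b_", vB$id)
  v <- rbind(pA$variants, vB)
  D <- cbind(pA$dosage, pB$dosage)
  colnames(D) <- v$id
  p <- genotype_panel(pA$sample_ids, v, D)
  attr(p, "ld_blocks") <- c(attr(pA, "ld_blocks"),
                            max(attr(pA, "ld_blocks")) +
                              attr(pB, "ld_blocks"))
  p
}
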