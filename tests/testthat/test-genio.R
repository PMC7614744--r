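test_that("bed payload encodes homozygote codes per the 2-bit convention", {
  p <- toy_panel(matrix(c(0, 2), 2, 1))
  prefix <- tempfile()
  write_plink(p, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  # ind1 dosage 0 -> code 11 (bits 0-1), ind2 dosage 2 -> code 00
  expect_identical(raw[4], as.raw(0x03))
  expect_length(raw, 4)
})

test_that("plink write/read round-trips panels, including missing codes", {
  set.seed(42)
  D <- matrix(sample(c(0, 1, 2, NA), 100 * 100, replace = TRUE,
                     prob = c(.4, .3, .25, .05)), 100, 100)
  p <- toy_panel(D)
  prefix <- tempfile()
  write_plink(p, prefix)
  p2 <- read_plink(prefix)
  expect_equal(unname(p$dosage), unname(p2$dosage))
  expect_equal(p$variants$pos, p2$variants$pos)
  expect_equal(p$variants$a1, p2$variants$a1)
  expect_equal(p$sample_ids, p2$sample_ids)

  # non-multiple-of-4 sample count exercises byte padding
  p3 <- toy_panel(D[1:13, 1:7])
  write_plink(p3, prefix)
  expect_equal(unname(read_plink(prefix)$dosage), unname(p3$dosage))
})

test_that("empty variant list yields valid zero-payload files", {
  p <- genotype_panel(c("a", "b"),
                      data.frame(chrom = character(0), pos = integer(0),
                                 id = character(0), a1 = character(0),
                                 a2 = character(0)),
                      matrix(numeric(0), 2, 0))
  prefix <- tempfile()
  write_plink(p, prefix)
  expect_identical(file.size(paste0(prefix, ".bed")), 3)
  p2 <- read_plink(prefix)
  expect_equal(ncol(p2$dosage), 0L)
})

test_that("corrupted magic bytes and size mismatches are rejected", {
  p <- toy_panel(matrix(c(0, 2), 2, 1))
  prefix <- tempfile()
  write_plink(p, prefix)
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x03)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x03, 0x03)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "payload")
})

test_that("read_sumstats converts OR to log scale and de-duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tSNP\tA1\tA2\tOR\tSE\tP\tN",
               "1\t100\trs1\tA\tG\t1.0\t0.1\t1.0\t1000",
               "1\t200\trs2\tA\tG\t2.0\t0.21067\t0.001\t1000",
               "1\t300\trs2\tA\tG\t1.5\t0.60147\t0.5\t1000",
               "1\t400\trs3\tA\tG\tNaN\t0.1\t0.5\t1000"),
             path)
  expect_warning(ss <- suppressMessages(read_sumstats(path)), "duplicated")
  expect_equal(ss$beta[ss$id == "rs1"], 0)
  expect_equal(ss$beta[ss$id == "rs2"], log(2), tolerance = 1e-4)
  expect_equal(nrow(ss), 2)          # dup dropped, NaN row dropped
  expect_equal(attr(ss, "n_dropped"), 2)
})

test_that("read_sumstats names the missing required column", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tSNP\tA1\tA2\tBETA\tP\tN",
               "1\t100\trs1\tA\tG\t0\t1\t100"), path)
  expect_error(suppressMessages(read_sumstats(path)), "SE")
})

test_that("simulated summary statistics round-trip through the readers", {
  cfg <- sim_config(n_individuals = 60, n_snps = 30, seed = 2)
  st <- simulate_multitrait_sumstats(cfg, simulate_genotypes(cfg))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(st$sumstats$ADHD, path)
  back <- read_sumstats(path)
  expect_equal(back$beta, st$sumstats$ADHD$beta, tolerance = 1e-12)
  expect_equal(back$p, st$sumstats$ADHD$p, tolerance = 1e-12)
  expect_equal(back$id, st$sumstats$ADHD$id)
})

test_that("HWE exact test matches the full-enumeration oracle", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 0), 1)   # monomorphic
  set.seed(7)
  for (i in 1:25) {
    cnt <- rmultinom(1, sample(5:60, 1), prob = c(.3, .45, .25))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("HWE p decreases monotonically with heterozygote excess", {
  # fixed allele counts (20 of each), increasing het count above HWE
  ps <- vapply(seq(10, 20, 2), function(h)
    hwe_exact_test((20 - h) / 2, h, (20 - h) / 2), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("negative genotype counts are rejected", {
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("variant QC attributes removals to the first failing criterion", {
  set.seed(1)
  # 10 SNPs: one rare (maf fail), one high-missing, one HWE violator
  n <- 400
  D <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  D[, 2] <- rbinom(n, 2, 0.005)                    # MAF < 0.01
  D[1:40, 3] <- NA                                 # 10% missing
  D[, 4] <- rep(c(0, 2), n / 2)                    # het deficit, HWE fail
  p <- toy_panel(D)
  r <- variant_qc_filter(p)
  expect_equal(r$report$n_removed, c(1, 1, 1))
  expect_equal(sum(r$report$n_removed),
               ncol(p$dosage) - ncol(r$object$dosage))
  expect_false(any(c("v002", "v003", "v004") %in% r$object$variants$id))

  # all-pass panel reports zeros, and the filter is idempotent
  r2 <- variant_qc_filter(r$object)
  expect_equal(r2$report$n_removed, c(0, 0, 0))
  expect_equal(r2$object$variants$id, r$object$variants$id)
})

test_that("sumstats QC filters on MAF and INFO", {
  p <- toy_panel(matrix(rbinom(200 * 4, 2, 0.3), 200, 4))
  ss <- toy_sumstats(p, rep(0.5, 4))
  ss$freq <- c(0.009, 0.011, 0.3, 0.3)
  ss$info <- c(1, 1, 0.85, 0.95)
  r <- variant_qc_filter(ss)
  expect_equal(r$object$id, c("v002", "v004"))
  expect_equal(r$report$n_removed, c(1, 1))
})

test_that("LD pruning matches the brute-force greedy oracle", {
  # duplicated columns give exact r2 = 1 pairs
  set.seed(3)
  base <- matrix(rbinom(60 * 6, 2, 0.4), 60, 6)
  D <- cbind(base[, 1], base[, 1], base[, 2:6],
             matrix(rbinom(60 * 3, 2, 0.4), 60, 3))
  p <- toy_panel(D, pos = c(1000, 2000, 5000, 9000, 15000, 22000, 30000,
                            41000, 52000, 300000))
  kept <- ld_prune(p, window_kb = 50, r2_max = 0.5)
  Xs <- scale(D)
  R <- crossprod(Xs) / (nrow(D) - 1)
  oracle <- prune_oracle(p$variants$pos, R, 0.5, 50000)
  expect_equal(kept, p$variants$id[oracle])
  # the duplicate pair lost its later member
  expect_false("v002" %in% kept)
  # independent SNPs all retained
  h <- hadamard_panel(4)
  expect_equal(ld_prune(h), h$variants$id)
  # idempotence
  sub <- subset_panel(p, variants = kept)
  expect_equal(ld_prune(sub, 50, 5, 0.5), kept)
})

test_that("PCA filter removes a planted outlier and leaves PCs orthogonal", {
  set.seed(5)
  D <- matrix(rbinom(80 * 60, 2, 0.3), 80, 60)
  D[1, ] <- rbinom(60, 2, 0.95)   # planted divergent individual
  p <- toy_panel(D)
  r <- pca_ancestry_filter(p, n_pcs = 4, sd_limit = 4)
  expect_true("s001" %in% r$removed)
  G <- crossprod(r$pcs)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(pca_ancestry_filter(p, n_pcs = 100), "n_pcs")
})

test_that("homogeneous panels rarely lose samples to the PCA filter", {
  removed <- vapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 60, n_snps = 80, ld_rho = 0, seed = s)
    length(pca_ancestry_filter(simulate_genotypes(cfg))$removed)
  }, numeric(1))
  expect_gte(mean(removed == 0), 0.9)
})

test_that("IBD pi-hat matches hand-computed method-of-moments algebra", {
  # 3-SNP pair, worked through the IBS -> IBD equations independently
  D <- rbind(c(0, 1, 2), c(0, 1, 0))
  p <- toy_panel(D)
  fr <- colMeans(D) / 2
  q <- 1 - fr
  ibs <- c(sum(abs(D[1, ] - D[2, ]) == 2), sum(abs(D[1, ] - D[2, ]) == 1),
           sum(D[1, ] == D[2, ]))
  z0 <- ibs[1] / sum(2 * fr^2 * q^2)
  z1 <- (ibs[2] - z0 * sum(4 * fr^3 * q + 4 * fr * q^3)) / sum(2 * fr * q)
  z2 <- (ibs[3] - z0 * sum(fr^4 + q^4 + 4 * fr^2 * q^2) -
           z1 * sum(fr^2 + q^2)) / 3
  z <- pmax(c(z0, z1, z2), 0); z <- z / sum(z)
  expected <- z[3] + z[2] / 2
  r <- ibd_filter(p, pi_hat_max = 2)  # threshold high: estimation only
  expect_equal(r$pi_hat$pi_hat, expected, tolerance = 1e-12)
})

test_that("full sibs are flagged and unrelated panels pass", {
  set.seed(9)
  m <- 3000
  fr <- runif(m, 0.2, 0.5)
  # parents as pairs of haplotypes; two sibs inherit one haplotype per parent
  pa <- cbind(rbinom(m, 1, fr), rbinom(m, 1, fr))
  mo <- cbind(rbinom(m, 1, fr), rbinom(m, 1, fr))
  pick <- function() pa[cbind(seq_len(m), sample(1:2, m, TRUE))] +
    mo[cbind(seq_len(m), sample(1:2, m, TRUE))]
  sib1 <- pick(); sib2 <- pick()
  others <- t(replicate(6, rbinom(m, 2, fr)))
  p <- toy_panel(rbind(sib1, sib2, others))
  r <- ibd_filter(p)
  sib_pair <- r$pi_hat[r$pi_hat$id1 == "s001" & r$pi_hat$id2 == "s002", ]
  expect_lt(abs(sib_pair$pi_hat - 0.5), 0.1)
  expect_true(any(c("s001", "s002") %in% r$removed))
  # removing the sib resolves everything: no unrelated casualties
  expect_lte(length(r$removed), 2)
})
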