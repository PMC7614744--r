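test_that("config invariants are enforced with named errors", {
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(ld_rho = -0.1), "ld_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(n_individuals = 1), "n_individuals")
  expect_error(sim_config(prop_prenatal = 0.6, prop_postnatal = 0.6),
               "prop_prenatal")
  expect_error(sim_config(causal_partition = c("XXX", "prenatal")),
               "causal_partition")
  bad_phi <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sim_config(factor_corr = bad_phi), "factor_corr")
  L <- default_factor_loadings() * 1.6   # communalities exceed 1
  expect_error(sim_config(factor_loadings = L), "variance")
})

test_that("genotypes are 0/1/2, in HWE, with allele frequency in range", {
  cfg <- sim_config(n_individuals = 10000, n_snps = 120,
                    maf_range = c(0.3, 0.3), seed = 8)
  p <- simulate_genotypes(cfg)
  expect_true(all(p$dosage %in% c(0, 1, 2)))
  f <- allele_freq(p)
  expect_gte(mean(f > 0.28 & f < 0.32), 0.99)
  gc <- cbind(colSums(p$dosage == 2), colSums(p$dosage == 1),
              colSums(p$dosage == 0))
  hwe <- vapply(seq_len(nrow(gc)),
                function(j) hwe_exact_test(gc[j, 1], gc[j, 2], gc[j, 3]),
                numeric(1))
  expect_gte(mean(hwe >= 1e-5), 0.999)
  for (ch in unique(p$variants$chrom))
    expect_false(is.unsorted(p$variants$pos[p$variants$chrom == ch],
                             strictly = TRUE))
})

test_that("ld_rho = 0 gives uncorrelated dosages; blocks are independent", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 60, ld_rho = 0, seed = 4)
  p <- simulate_genotypes(cfg)
  R <- cor(p$dosage)
  expect_lt(abs(mean(R[upper.tri(R)])), 0.02)

  # with LD, adjacent same-block SNPs correlate; cross-block pairs do not
  cfg2 <- sim_config(n_individuals = 3000, n_snps = 40, ld_rho = 0.9,
                     ld_block_size = 20, seed = 4)
  p2 <- simulate_genotypes(cfg2)
  R2 <- cor(p2$dosage)
  within <- mean(R2[cbind(1:19, 2:20)])
  across <- abs(mean(R2[1:20, 21:40]))
  expect_gt(within, 0.5)
  expect_lt(across, 0.05)
})

test_that("null GWAS gives mean chi-square near 1 and planted h2 inflates
           it by the LDSC expectation", {
  cfg <- sim_config(n_individuals = 300, n_snps = 20000, seed = 13,
                    h2_per_disorder = rep(0, 8))
  p <- simulate_genotypes(cfg)
  s0 <- simulate_multitrait_sumstats(cfg, p)
  chi2 <- (s0$sumstats$ADHD$beta / s0$sumstats$ADHD$se)^2
  expect_lt(abs(mean(chi2) - 1), 0.02)

  cfg2 <- sim_config(n_individuals = 300, n_snps = 20000, seed = 13,
                     h2_per_disorder = rep(0.4, 8),
                     n_gwas_per_disorder = rep(50000, 8))
  s1 <- simulate_multitrait_sumstats(cfg2, p)
  chi2 <- (s1$sumstats$ADHD$beta / s1$sumstats$ADHD$se)^2
  l <- compute_ld_scores(p)$ldscore
  expected <- 1 + 50000 * 0.4 * mean(l) / 20000
  expect_lt(abs(mean(chi2) - expected) / expected, 0.05)
})

test_that("cross-disorder covariance of true effects matches the planted
           factor structure", {
  L <- cbind(c(0.7, 0.7), c(0, 0))[, 1, drop = FALSE]
  cfg <- sim_config(n_individuals = 100, n_snps = 20000, seed = 21,
                    disorders = c("D1", "D2"),
                    factor_loadings = matrix(c(0.7, 0.7), 2, 1),
                    factor_corr = matrix(1, 1, 1),
                    h2_per_disorder = c(0.5, 0.5),
                    n_gwas_per_disorder = c(1e4, 1e4))
  st <- simulate_multitrait_sumstats(cfg, simulate_genotypes(cfg))
  r <- cor(st$truth$snp_effects[, 1], st$truth$snp_effects[, 2])
  expect_lt(abs(r - 0.49), 0.05)
  # truth record genetic covariance agrees with its own effect vectors
  emp_cov <- cov(st$truth$snp_effects) * 20000
  expect_equal(unname(emp_cov), unname(st$truth$genetic_cov),
               tolerance = 0.1)
})

test_that("overloaded factor structures are rejected", {
  cfg <- sim_config(seed = 1, n_individuals = 50, n_snps = 40)
  cfg$factor_loadings <- default_factor_loadings() * 1.6
  p <- simulate_genotypes(cfg)
  expect_error(simulate_multitrait_sumstats(cfg, p), "variance")
})

test_that("expression atlas plants detectable timing classes in 6 regions", {
  cfg <- sim_config(n_genes = 400, seed = 31)
  ea <- simulate_expression_atlas(cfg)
  expect_setequal(unique(ea$atlas$samples$region),
                  c("CBC", "AMY", "MDTHAL", "STR", "HIP", "NCX"))
  expect_true(all(ea$atlas$expr >= 0))
  # planted prenatal genes give positive t statistics nearly always
  E <- log2(ea$atlas$expr + 1)
  meta <- ea$atlas$samples
  cbc <- meta$region == "CBC"
  pre_genes <- rownames(ea$truth)[ea$truth[, "CBC"] == "prenatal"]
  tstat <- vapply(pre_genes, function(g)
    t.test(E[g, cbc & meta$prenatal], E[g, cbc & !meta$prenatal])$statistic,
    numeric(1))
  expect_gte(mean(tstat > 0), 0.95)
})

test_that("a null atlas yields uniform pre/post p-values", {
  cfg <- sim_config(n_genes = 400, expr_effect = 0, seed = 32)
  ea <- simulate_expression_atlas(cfg)
  E <- log2(ea$atlas$expr + 1)
  meta <- ea$atlas$samples
  cbc <- meta$region == "CBC"
  ps <- apply(E[, cbc], 1, function(y)
    t.test(y[meta$prenatal[cbc]], y[!meta$prenatal[cbc]])$p.value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("atlas rejects fewer than 2 donors per window", {
  expect_error(sim_config(n_donors_pre = 1), "donors")
})

test_that("phenotype scales reproduce the target correlation matrix and
           planted genetic variance share", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 600, n_genes = 80,
                    seed = 17)
  st <- simulate_study(cfg)
  C_emp <- cor(as.matrix(st$pheno[, colnames(cfg$pheno_target_corr)]))
  expect_lt(max(abs(C_emp - cfg$pheno_target_corr)), 0.05)
  r2 <- summary(lm(st$pheno$total ~ st$truth$liability))$r.squared
  expect_lt(abs(r2 - cfg$pgs_effect_r2), 0.015)
  expect_equal(st$pheno$clinical, st$pheno$total >= 64)
  expect_true(all(c("age", "sex", "site", "PC1", "PC5") %in%
                    names(st$pheno)))
})

test_that("with no genetic effect the liability does not predict Total", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 400, n_snps = 200, n_genes = 40,
                      pgs_effect_r2 = 0, seed = s)
    st <- simulate_study(cfg)
    g <- st$truth$liability
    if (sd(g) == 0) return(FALSE)  # empty causal partition: trivially null
    abs(summary(lm(st$pheno$total ~ g))$coefficients[2, "t value"]) >= 2
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("default phenotype correlations span the reported ranges", {
  C <- default_pheno_corr()
  cbcl <- setdiff(colnames(C), "psychosis")
  off <- C[cbcl, cbcl][upper.tri(C[cbcl, cbcl])]
  expect_true(all(off >= 0.29 & off <= 0.85))
  expect_true(all(C["psychosis", cbcl] >= 0.07 &
                    C["psychosis", cbcl] <= 0.14))
})

test_that("gene map tiles disjoint strand-labelled intervals", {
  cfg <- sim_config(n_individuals = 50, n_snps = 200, n_genes = 25, seed = 3)
  p <- simulate_genotypes(cfg)
  gm <- simulate_gene_map(cfg, p)
  expect_equal(nrow(gm), 25)
  expect_false(anyDuplicated(gm$gene_id) > 0)
  for (ch in unique(gm$chrom)) {
    g <- gm[gm$chrom == ch, ]
    ord <- order(g$start)
    if (nrow(g) > 1)
      expect_true(all(g$end[ord][-nrow(g)] < g$start[ord][-1]))
  }
  expect_true(all(gm$strand %in% c("+", "-")))
  expect_true(all(gm$start <= gm$end))

  # genes spanning each whole chromosome annotate every SNP
  gm1 <- do.call(rbind, lapply(unique(p$variants$chrom), function(ch) {
    pos <- p$variants$pos[p$variants$chrom == ch]
    data.frame(gene_id = paste0("g", ch), chrom = ch,
               start = min(pos), end = max(pos), strand = "+")
  }))
  an <- annotate_snps_to_genes(p$variants, gm1)
  expect_setequal(an$map$snp_id, p$variants$id)

  expect_error(simulate_gene_map(sim_config(n_genes = 1e9), p), "range")
})

test_that("fixed seeds reproduce every emitted file byte-for-byte", {
  cfg <- sim_config(n_individuals = 40, n_snps = 60, n_genes = 10,
                    n_donors_pre = 3, n_donors_post = 3, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  }
})
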