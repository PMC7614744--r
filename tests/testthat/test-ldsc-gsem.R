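test_that("LD scores match a brute-force double-loop oracle", {
  set.seed(12)
  D <- matrix(rbinom(50 * 5, 2, 0.4), 50, 5)
  D <- cbind(D, D[, 1])  # a perfect-LD pair
  p <- toy_panel(D, pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  got <- compute_ld_scores(p, window_kb = 1000)
  n <- nrow(D)
  Xs <- scale(D)
  oracle <- vapply(1:6, function(j) {
    sum(vapply(1:6, function(k) {
      r2 <- (sum(Xs[, j] * Xs[, k]) / (n - 1))^2
      r2 - (1 - r2) / (n - 2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(got$ldscore, oracle, tolerance = 1e-10)

  # isolated SNP: self term only
  p1 <- toy_panel(D[, 1, drop = FALSE])
  expect_equal(compute_ld_scores(p1)$ldscore, 1, tolerance = 1e-12)
  # perfectly correlated pair alone: each scores exactly 2
  p2 <- toy_panel(D[, c(1, 6)])
  expect_equal(compute_ld_scores(p2)$ldscore, c(2, 2), tolerance = 1e-10)

  expect_error(compute_ld_scores(toy_panel(D[1:2, ])), "n >= 3")
})

test_that("ldsc_regression rejects under-sized or degenerate inputs", {
  cfg <- sim_config(n_individuals = 50, n_snps = 100, seed = 1)
  p <- simulate_genotypes(cfg)
  st <- simulate_multitrait_sumstats(cfg, p)
  ld <- compute_ld_scores(p)
  expect_error(ldsc_regression(st$sumstats[1], ld, n_blocks = 200),
               "jackknife block")
  ld$ldscore[] <- 1
  expect_error(ldsc_regression(st$sumstats[1], ld, n_blocks = 10),
               "constant")
})

ldsc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulate_ldsc_calibration_panel(n_individuals = 400,
                                           n_iso = 2000, n_block = 6000,
                                           seed = 77)
      cfg <- sim_config(n_individuals = 400, n_snps = 8000, seed = 78,
                        disorders = c("D1", "D2"),
                        factor_loadings = matrix(c(0.7, 0.7), 2, 1),
                        factor_corr = matrix(1, 1, 1),
                        h2_per_disorder = c(0.4, 0.4),
                        n_gwas_per_disorder = c(5e4, 5e4))
      cache <<- list(cfg = cfg, p = p,
                     st = simulate_multitrait_sumstats(cfg, p),
                     ld = compute_ld_scores(p, window_kb = 250))
    }
    cache
  }
})

test_that("ldsc_regression recovers planted h2 and genetic correlation", {
  fx <- ldsc_fixture()
  g <- ldsc_regression(fx$st$sumstats, fx$ld, n_blocks = 100)
  expect_lt(abs(g$S["D1", "D1"] - 0.4), 0.08)
  expect_lt(abs(g$intercepts["D1", "D1"] - 1), 0.3)
  rg <- g$S[1, 2] / sqrt(g$S[1, 1] * g$S[2, 2])
  expect_lt(abs(rg - 0.49), 0.12)
  expect_equal(dim(g$V), c(3, 3))
  expect_true(isSymmetric(g$V))
  ev <- eigen(g$V, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("S is invariant to trait order and to allele flips", {
  fx <- ldsc_fixture()
  g <- ldsc_regression(fx$st$sumstats, fx$ld, n_blocks = 100)
  g_rev <- ldsc_regression(rev(fx$st$sumstats), fx$ld, n_blocks = 100)
  expect_equal(g$S, g_rev$S[rownames(g$S), colnames(g$S)], tolerance = 1e-10)

  flipped <- fx$st$sumstats
  s2 <- flipped$D2
  tmp <- s2$a1; s2$a1 <- s2$a2; s2$a2 <- tmp
  s2$beta <- -s2$beta
  s2$freq <- 1 - s2$freq
  flipped$D2 <- s2
  g_flip <- ldsc_regression(flipped, fx$ld, n_blocks = 100)
  expect_equal(g$S, g_flip$S, tolerance = 1e-10)
})

test_that("EFA recovers a planted 3-factor structure after promax", {
  L <- default_factor_loadings()
  Phi <- default_factor_corr()
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(rownames(L), rownames(L))
  fs <- efa_promax(R, 3)
  cong <- vapply(1:3, function(f)
    max(abs(apply(fs$loadings, 2, tucker_congruence, y = L[, f]))),
    numeric(1))
  expect_true(all(cong >= 0.98))
  expect_true(fs$variance_explained > 0.4 && fs$variance_explained <= 1)
})

test_that("sub-cutoff loadings are masked and identity S explains little", {
  # planted small cross-loading of 0.15 must be masked at the 0.2 cutoff
  L <- cbind(c(0.8, 0.8, 0.8, 0.15, 0, 0), c(0.15, 0, 0, 0.8, 0.8, 0.8))
  R <- tcrossprod(L)
  diag(R) <- 1
  fs <- efa_promax(R, 2)
  # identify which rotated column matches each planted factor
  m1 <- which.max(abs(apply(fs$loadings, 2, tucker_congruence, y = L[, 1])))
  expect_equal(unname(fs$loadings_masked[4, m1]), 0)
  expect_gt(abs(fs$loadings_masked[1, m1]), 0.2)

  fs_id <- efa_promax(diag(8), 3)
  expect_lte(fs_id$variance_explained, 3 / 8 + 0.05)

  expect_error(efa_promax(diag(3), 3), "n_factors")
  expect_error(efa_promax(matrix(NA_real_, 2, 2), 1), "finite")
})

test_that("CFA solves the just-identified tetrad exactly and flags
           saturated fits", {
  l3 <- c(0.8, 0.7, 0.6)
  S3 <- tcrossprod(l3)
  diag(S3) <- 1
  dimnames(S3) <- list(c("X1", "X2", "X3"), c("X1", "X2", "X3"))
  fit <- cfa_wls(S3, diag(0.001, 6), cfa_spec(list(F1 = c("X1", "X2", "X3"))))
  expect_equal(fit$estimates$estimate[1:3], l3, tolerance = 1e-3)
  expect_equal(fit$chi2, 0)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$srmr, 1e-4)
  expect_equal(fit$df, 0)
})

test_that("CFA degrees of freedom and fit ordering behave as expected", {
  L <- default_factor_loadings()
  Phi <- default_factor_corr()
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  S <- 0.4 * R
  dimnames(S) <- list(rownames(L), rownames(L))
  V <- diag(0.001, 36)
  good <- cfa_wls(S, V)
  expect_equal(good$df, 15)   # 36 moments - 21 free parameters
  expect_lt(good$chi2, 1)     # S exactly factor-structured
  bad <- cfa_wls(S, V, cfa_spec(list(
    NDV = c("AN", "BIP", "ASD"), COMP = c("ADHD", "SCZ", "OCD"),
    MP = c("MDD", "TS"))))
  expect_gt(bad$chi2, good$chi2)
  expect_lt(bad$cfi, good$cfi)
  expect_gt(bad$srmr, good$srmr)

  expect_error(cfa_wls(S, V, cfa_spec(list(F1 = c("ADHD", "ASD"),
                                           F2 = c("ADHD",  "MDD")))),
               "identified")
})

test_that("common-factor GWAS matches the path-algebra closed form", {
  # one factor, equal loadings, equal standardized SNP effects: the
  # factor beta is b / lambda
  l <- 0.7
  S <- matrix(l^2, 3, 3)
  diag(S) <- 1
  dimnames(S) <- list(c("T1", "T2", "T3"), c("T1", "T2", "T3"))
  p <- hadamard_panel(4)
  f <- allele_freq(p)
  n_gwas <- 10000
  b_std <- 0.03
  z <- b_std * sqrt(n_gwas * 2 * f * (1 - f))
  ss <- list(T1 = toy_sumstats(p, z, n_gwas),
             T2 = toy_sumstats(p, z, n_gwas),
             T3 = toy_sumstats(p, z, n_gwas))
  fg <- common_factor_gwas(S, diag(1e-4, 6),
                           cfa_spec(list(F1 = c("T1", "T2", "T3"))),
                           ss, data.frame(id = p$variants$id, freq = f))
  b_in <- ss$T1$beta   # equal observed per-allele betas across indicators
  expect_equal(fg$F1$beta, b_in / l, tolerance = 1e-3)
})

test_that("the three-cluster default emits exactly three factors", {
  cfg <- sim_config(n_individuals = 200, n_snps = 400, seed = 3)
  p <- simulate_genotypes(cfg)
  st <- simulate_multitrait_sumstats(cfg, p)
  fg <- common_factor_gwas(st$truth$genetic_cov, diag(0.002, 36),
                           default_cfa_spec(), st$sumstats,
                           data.frame(id = p$variants$id,
                                      freq = allele_freq(p)))
  expect_named(fg, c("NDV", "COMP", "MP"))
  for (f in fg) {
    expect_s3_class(f, "sumstats")
    z <- f$beta / f$se
    expect_equal(f$p, pmax(2 * pnorm(-abs(z)), 1e-300), tolerance = 1e-12)
  }
})
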