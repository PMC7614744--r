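#' Multivariable LD-score regression with block-jackknife sampling
#' covariance
#'
#' Univariate fits regress each trait's chi-square statistics on LD
#' scores (weighted, free intercept), giving SNP heritability from the
#' slope; bivariate fits regress z1*z2 products, giving genetic
#' covariance and a cross-trait intercept. The sampling covariance V of
#' vech(S) comes from a delete-one-block jackknife over contiguous SNP
#' blocks. Input traits are intersected on variant id and allele-aligned
#' to the first trait (swapped alleles flip beta; strand-ambiguous A/T
#' and C/G variants are dropped).
#'
#' Weights follow the standard LDSC scheme: the inverse of the LD score
#' times the squared expected statistic variance from a first-pass fit.
#'
#' @param ss_list named list of [sumstats()] objects.
#' @param ldscores data.frame from [compute_ld_scores()].
#' @param n_blocks number of jackknife blocks (default 200).
#' @return object of class `genetic_covariance`: S (k x k, diagonal h2),
#'   V (sampling covariance of vech(S), smoothed to positive-definite if
#'   needed and flagged), intercepts matrix, m (SNPs used), n (per-trait
#'   median N).
#' @export
ldsc_regression <- function(ss_list, ldscores, n_blocks = 200) {
  k <- length(ss_list)
  stopifnot(k >= 1)
  traits <- names(ss_list) %||% paste0("trait", seq_len(k))

  ref <- ss_list[[1]][, c("id", "a1", "a2")]
  amb <- is_ambiguous_pair(ref$a1, ref$a2)
  ref <- ref[!amb, , drop = FALSE]
  aligned <- lapply(ss_list, function(s) align_to_reference(s, ref)$ss)
  ids <- Reduce(intersect, lapply(aligned, function(s) s$id))
  ids <- intersect(ids, ldscores$id)
  aligned <- lapply(aligned, function(s) s[match(ids, s$id), , drop = FALSE])
  ord <- order(aligned[[1]]$chrom, aligned[[1]]$pos)
  aligned <- lapply(aligned, function(s) s[ord, , drop = FALSE])
  l <- ldscores$ldscore[match(aligned[[1]]$id, ldscores$id)]
  m <- length(l)
  if (m < 2 * n_blocks)
    stop("need at least 2 SNPs per jackknife block (", 2 * n_blocks,
         "); got ", m)
  if (stats::sd(l) == 0) stop("LD scores are constant; slope unidentifiable")

  Zm <- vapply(aligned, function(s) s$beta / s$se, numeric(m))
  Nm <- vapply(aligned, function(s) stats::median(s$n), numeric(1))

  block <- ceiling(seq_len(m) / (m / n_blocks))
  X <- cbind(1, l)

  # first pass: per-trait slope for weighting
  c1 <- numeric(k)
  for (j in seq_len(k)) {
    w0 <- 1 / pmax(l, 1)
    fit <- stats::lm.wfit(X, Zm[, j]^2, w0)
    c1[j] <- max(fit$coefficients[2], 0)
  }

  p_star <- k * (k + 1) / 2
  est <- matrix(NA_real_, 1, p_star)
  jk <- matrix(NA_real_, n_blocks, p_star)
  S <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  icept <- matrix(NA_real_, k, k, dimnames = list(traits, traits))

  col_of <- function(i, j) {
    # column-major lower-triangle vech index for (i >= j)
    (j - 1) * k - (j - 1) * j / 2 + i
  }

  for (j in seq_len(k)) {
    for (i in j:k) {
      y <- Zm[, i] * Zm[, j]
      w <- 1 / (pmax(l, 1) * (1 + c1[i] * l) * (1 + c1[j] * l))
      XW <- X * w
      A <- crossprod(XW, X)
      b <- crossprod(XW, y)
      th <- solve(A, b)
      scale_ij <- m / sqrt(Nm[i] * Nm[j])
      cc <- col_of(i, j)
      est[1, cc] <- th[2] * scale_ij
      icept[i, j] <- icept[j, i] <- th[1]
      S[i, j] <- S[j, i] <- th[2] * scale_ij
      # delete-one-block estimates from per-block sufficient statistics
      for (bb in seq_len(n_blocks)) {
        sel <- block == bb
        Ab <- crossprod(X[sel, , drop = FALSE] * w[sel], X[sel, , drop = FALSE])
        bb2 <- crossprod(X[sel, , drop = FALSE] * w[sel], y[sel])
        thb <- solve(A - Ab, b - bb2)
        jk[bb, cc] <- thb[2] * scale_ij
      }
    }
  }

  dev <- sweep(jk, 2, colMeans(jk))
  V <- (n_blocks - 1) / n_blocks * crossprod(dev)
  sm <- smooth_to_pd(V)
  structure(list(S = S, V = sm$mat, V_smoothed = sm$smoothed,
                 intercepts = icept, m = m, n = Nm, traits = traits,
                 n_blocks = n_blocks),
            class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat("genetic_covariance over", length(x$traits), "traits,", x$m,
      "SNPs,", x$n_blocks, "jackknife blocks\n")
  cat("  h2:", paste(sprintf("%s=%.3f", x$traits, diag(x$S)),
                     collapse = ", "), "\n")
  if (x$V_smoothed) cat("  note: V smoothed to positive-definite\n")
  invisible(x)
}
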