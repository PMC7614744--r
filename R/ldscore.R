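#' Compute LD scores from a reference panel
#'
#' The LD score of variant j is the sum, over variants within
#' `window_kb` on the same chromosome (including j itself), of the
#' adjusted squared dosage correlation r2_adj = r2 - (1 - r2) / (n - 2),
#' an approximately unbiased estimate of the population r2. Missing
#' dosages are mean-imputed before standardization.
#'
#' @param panel a QC'd [genotype_panel()] with n >= 3 samples.
#' @param window_kb window radius in kb (default 1000).
#' @return data.frame with columns id, ldscore.
#' @export
compute_ld_scores <- function(panel, window_kb = 1000) {
  n <- length(panel$sample_ids)
  if (n < 3) stop("compute_ld_scores needs n >= 3 samples")
  Xs <- standardize_dosage(panel$dosage)
  v <- panel$variants
  m <- nrow(v)
  l <- numeric(m)
  w <- window_kb * 1000
  chunk <- 256L
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    for (s in seq(1, length(idx), by = chunk)) {
      ci <- idx[s:min(s + chunk - 1L, length(idx))]
      cpos <- v$pos[ci]
      wi <- idx[pos >= min(cpos) - w & pos <= max(cpos) + w]
      C <- crossprod(Xs[, ci, drop = FALSE], Xs[, wi, drop = FALSE]) / (n - 1L)
      r2 <- C^2
      adj <- r2 - (1 - r2) / (n - 2L)
      inwin <- abs(outer(cpos, v$pos[wi], "-")) <= w
      l[ci] <- rowSums(adj * inwin)
    }
  }
  data.frame(id = v$id, ldscore = l, stringsAsFactors = FALSE)
}
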