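#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a dosage matrix
#'
#' Columns are centred and scaled; missing entries are replaced by the
#' column mean before scaling (so they contribute zero after centring).
#' Zero-variance columns are set to all-zero rather than NaN.
#'
#' @param dosage numeric matrix, individuals x variants, entries 0/1/2 or NA.
#' @return numeric matrix of the same shape.
#' @keywords internal
standardize_dosage <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  X <- sweep(dosage, 2, mu)
  X[is.na(X)] <- 0
  s <- sqrt(colSums(X^2) / pmax(nrow(X) - 1L, 1L))
  s[s == 0] <- Inf
  sweep(X, 2, s, "/")
}

#' Half-vectorization of a symmetric matrix (column-major lower triangle)
#' @keywords internal
vech <- function(S) S[lower.tri(S, diag = TRUE)]

#' Inverse of [vech()]
#' @keywords internal
unvech <- function(v) {
  k <- (sqrt(8 * length(v) + 1) - 1) / 2
  stopifnot(k == round(k))
  S <- matrix(0, k, k)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

#' Nearest positive-definite smoothing by eigenvalue flooring
#'
#' Floors eigenvalues at `floor_frac` times the largest eigenvalue.
#' Returns the input untouched (with `smoothed = FALSE`) when already
#' positive-definite.
#' @keywords internal
smooth_to_pd <- function(S, floor_frac = 1e-9) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lo <- floor_frac * max(e$values)
  if (all(e$values > lo)) return(list(mat = S, smoothed = FALSE))
  vals <- pmax(e$values, lo)
  M <- e$vectors %*% (vals * t(e$vectors))
  list(mat = (M + t(M)) / 2, smoothed = TRUE)
}

#' Is an allele pair strand-ambiguous (A/T or C/G)?
#' @keywords internal
is_ambiguous_pair <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Align one summary-statistics table to reference alleles
#'
#' Matches rows of `ss` to reference variants by id. Rows whose alleles
#' match the reference orientation are kept as-is; swapped rows have beta
#' (and freq) flipped; strand-ambiguous or allele-mismatched rows are
#' dropped.
#'
#' @param ss a `sumstats` object.
#' @param ref data.frame with columns id, a1, a2.
#' @param drop_ambiguous drop A/T and C/G variants (default TRUE).
#' @return list(ss = aligned sumstats, n_flipped, n_dropped)
#' @export
align_to_reference <- function(ss, ref, drop_ambiguous = TRUE) {
  idx <- match(ss$id, ref$id)
  keep <- !is.na(idx)
  ss <- ss[keep, , drop = FALSE]
  idx <- idx[keep]
  same <- ss$a1 == ref$a1[idx] & ss$a2 == ref$a2[idx]
  swap <- ss$a1 == ref$a2[idx] & ss$a2 == ref$a1[idx]
  amb <- is_ambiguous_pair(ss$a1, ss$a2)
  ok <- (same | swap) & !(drop_ambiguous & amb)
  n_dropped <- sum(!keep) + sum(!ok)
  ss <- ss[ok, , drop = FALSE]
  swap <- swap[ok]
  ss$beta[swap] <- -ss$beta[swap]
  if (!is.null(ss$freq)) ss$freq[swap] <- 1 - ss$freq[swap]
  a1 <- ss$a1
  ss$a1[swap] <- ss$a2[swap]
  ss$a2[swap] <- a1[swap]
  list(ss = ss, swapped = swap, n_flipped = sum(swap), n_dropped = n_dropped)
}

#' Tucker congruence coefficient between two loading vectors
#'
#' @param x,y numeric loading vectors of equal length.
#' @return the congruence coefficient in [-1, 1].
#' @export
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
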