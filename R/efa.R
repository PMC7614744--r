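#' Exploratory factor analysis of a genetic covariance matrix with
#' promax rotation
#'
#' The genetic covariance S is standardized to correlation scale,
#' factored by minimum-residual extraction (uniquenesses optimized so the
#' off-diagonal residuals of the reduced correlation matrix are smallest
#' in least squares), and obliquely rotated with promax (power 4).
#' Loadings below `loading_cutoff` in absolute value are masked to zero
#' in `loadings_masked`, which defines factor membership downstream.
#'
#' @param S symmetric genetic covariance (or correlation) matrix.
#' @param n_factors number of factors (default 3; must be < ncol(S)).
#' @param loading_cutoff absolute loading below which an indicator does
#'   not define a factor (default 0.2).
#' @return object of class `factor_solution`: pattern `loadings`,
#'   `loadings_masked`, factor correlations `Phi`, `communalities`,
#'   `variance_explained` (proportion of total standardized genetic
#'   variance), `uniquenesses`, and the applied `cutoff`.
#' @export
efa_promax <- function(S, n_factors = 3, loading_cutoff = 0.2) {
  if (any(!is.finite(S))) stop("S contains non-finite values")
  k <- ncol(S)
  if (n_factors >= k) stop("n_factors must be smaller than the number of traits")
  R <- stats::cov2cor((S + t(S)) / 2)

  extract <- function(psi) {
    Rc <- R
    diag(Rc) <- 1 - psi
    e <- eigen(Rc, symmetric = TRUE)
    q <- seq_len(n_factors)
    Lw <- e$vectors[, q, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[q], 0)), n_factors)
    Lw
  }
  objective <- function(psi) {
    Lw <- extract(psi)
    resid <- R - tcrossprod(Lw)
    diag(resid) <- 0
    sum(resid^2)
  }
  # start uniquenesses at 1 - SMC where invertible
  psi0 <- tryCatch(1 / diag(solve(R)), error = function(e) rep(0.5, k))
  psi0 <- pmin(pmax(psi0, 0.05), 0.95)
  opt <- stats::optim(psi0, objective, method = "L-BFGS-B",
                      lower = 1e-3, upper = 1)
  Lw <- extract(opt$par)

  if (n_factors == 1 || max(abs(Lw)) < 1e-4) {
    P <- Lw
    Phi <- diag(n_factors)
  } else {
    # a fixed generic-position pre-rotation keeps varimax off the exact
    # symmetric stationary points that arise for perfectly balanced
    # planted structures (the final solution is rotation-invariant)
    Q0 <- qr.Q(qr(matrix(sin(seq_len(n_factors^2)), n_factors)))
    Lw <- Lw %*% Q0
    # promax operates on the varimax solution; rotation can degenerate
    # when there is no common variance (rows of zero loadings), in which
    # case the unrotated solution is returned
    rot <- tryCatch({
      vm <- stats::varimax(Lw)
      pm <- stats::promax(unclass(vm$loadings), m = 4)
      rotmat <- vm$rotmat %*% pm$rotmat
      Phi <- solve(crossprod(rotmat))
      list(P = unclass(pm$loadings),
           Phi = stats::cov2cor((Phi + t(Phi)) / 2))
    }, error = function(e) list(P = Lw, Phi = diag(n_factors)))
    P <- rot$P
    Phi <- rot$Phi
  }
  rownames(P) <- rownames(R) %||% colnames(S)
  colnames(P) <- paste0("F", seq_len(n_factors))
  dimnames(Phi) <- list(colnames(P), colnames(P))

  h2 <- diag(P %*% Phi %*% t(P))
  masked <- P
  masked[abs(masked) < loading_cutoff] <- 0

  structure(list(loadings = P, loadings_masked = masked, Phi = Phi,
                 communalities = h2,
                 variance_explained = sum(h2) / k,
                 uniquenesses = opt$par, cutoff = loading_cutoff,
                 converged = opt$convergence == 0),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat("factor_solution:", ncol(x$loadings), "factors,",
      sprintf("%.1f%%", 100 * x$variance_explained),
      "of standardized genetic variance\n")
  print(round(x$loadings, digits))
  cat("factor correlations:\n")
  print(round(x$Phi, digits))
  invisible(x)
}
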