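#' Default correlated three-factor confirmatory model
#'
#' NDV = ADHD, ASD, MDD, TS; COMP = AN, OCD, TS; MP = BIP, MDD, SCZ;
#' factors freely correlated, factor variances fixed to 1.
#'
#' @return a `cfa_spec` list mapping factors to indicator names.
#' @export
default_cfa_spec <- function() {
  structure(list(factors = list(
    NDV = c("ADHD", "ASD", "MDD", "TS"),
    COMP = c("AN", "OCD", "TS"),
    MP = c("BIP", "MDD", "SCZ")
  ), correlated = TRUE), class = "cfa_spec")
}

#' Build a cfa_spec from a named list of indicator vectors
#' @param factors named list: factor name -> character vector of indicators.
#' @param correlated allow factor correlations (default TRUE).
#' @return a `cfa_spec`.
#' @export
cfa_spec <- function(factors, correlated = TRUE) {
  stopifnot(is.list(factors), length(names(factors)) == length(factors))
  structure(list(factors = factors, correlated = correlated),
            class = "cfa_spec")
}

cfa_layout <- function(S, spec) {
  traits <- colnames(S)
  fac <- names(spec$factors)
  nf <- length(fac)
  edges <- do.call(rbind, lapply(seq_len(nf), function(f) {
    ind <- spec$factors[[f]]
    miss <- setdiff(ind, traits)
    if (length(miss)) stop("model indicators absent from S: ",
                           paste(miss, collapse = ", "))
    data.frame(trait = match(ind, traits), factor = f)
  }))
  for (f in seq_len(nf)) {
    ind <- spec$factors[[f]]
    solo <- ind[vapply(ind, function(i)
      sum(vapply(spec$factors, function(g) i %in% g, logical(1))), integer(1)) == 1]
    if (length(solo) < 2)
      stop("factor ", fac[f], " has fewer than 2 unique indicators; ",
           "model not identified")
  }
  ncorr <- if (spec$correlated && nf > 1) nf * (nf - 1) / 2 else 0
  list(traits = traits, k = length(traits), nf = nf, edges = edges,
       ncorr = ncorr,
       q = nrow(edges) + ncorr + length(traits))
}

cfa_implied <- function(theta, lay) {
  k <- lay$k; nf <- lay$nf; ne <- nrow(lay$edges)
  Lam <- matrix(0, k, nf)
  Lam[cbind(lay$edges$trait, lay$edges$factor)] <- theta[seq_len(ne)]
  Phi <- diag(nf)
  if (lay$ncorr > 0) {
    rho <- theta[ne + seq_len(lay$ncorr)]
    Phi[lower.tri(Phi)] <- rho
    Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
  }
  Theta <- diag(theta[ne + lay$ncorr + seq_len(k)], k)
  Lam %*% Phi %*% t(Lam) + Theta
}

#' Confirmatory factor model on a genetic covariance matrix by weighted
#' least squares
#'
#' Minimizes the discrepancy between vech(S) and the model-implied
#' moments with weight matrix diag(V)^-1 (diagonally weighted least
#' squares; set `estimator = "WLS"` for the full inverse of V). The test
#' statistic is Browne's residual-based chi-square using the full
#' sampling covariance V, which is asymptotically chi-square on
#' p* - q degrees of freedom regardless of the fitting weights.
#' Parameter standard errors use the sandwich formula. CFI is computed
#' against an independence model (free variances only); SRMR on
#' correlation-scale residuals; AIC = chi2 + 2q.
#'
#' @param S k x k genetic covariance with trait dimnames.
#' @param V sampling covariance of vech(S), k(k+1)/2 square.
#' @param model_spec a [cfa_spec()] (default [default_cfa_spec()]).
#' @param estimator "DWLS" (default) or "WLS".
#' @return object of class `cfa_fit`.
#' @export
cfa_wls <- function(S, V, model_spec = default_cfa_spec(),
                    estimator = c("DWLS", "WLS")) {
  estimator <- match.arg(estimator)
  lay <- cfa_layout(S, model_spec)
  s <- vech(S)
  p_star <- length(s)
  stopifnot(nrow(V) == p_star, ncol(V) == p_star)
  W <- if (estimator == "DWLS") diag(1 / diag(V), p_star) else solve(V)

  ne <- nrow(lay$edges)
  start <- c(rep(sqrt(max(mean(diag(S)), 0.1) / 2), ne),
             rep(0.3, lay$ncorr),
             pmax(diag(S) / 2, 0.01))
  lower <- c(rep(-2, ne), rep(-0.98, lay$ncorr), rep(1e-8, lay$k))
  upper <- c(rep(2, ne), rep(0.98, lay$ncorr), rep(Inf, lay$k))

  fobj <- function(th) {
    r <- s - vech(cfa_implied(th, lay))
    drop(crossprod(r, W %*% r))
  }
  opt <- stats::nlminb(start, fobj, lower = lower, upper = upper,
                       control = list(iter.max = 2000, eval.max = 4000))
  th <- opt$par
  r <- s - vech(cfa_implied(th, lay))

  jac <- function(th, lay) {
    # central differences on vech(implied)
    h <- pmax(abs(th), 1) * 1e-6
    J <- matrix(0, p_star, length(th))
    for (i in seq_along(th)) {
      tp <- th; tp[i] <- tp[i] + h[i]
      tm <- th; tm[i] <- tm[i] - h[i]
      J[, i] <- (vech(cfa_implied(tp, lay)) - vech(cfa_implied(tm, lay))) /
        (2 * h[i])
    }
    J
  }
  Delta <- jac(th, lay)

  # sandwich SEs
  A <- crossprod(Delta, W %*% Delta)
  Ainv <- tryCatch(solve(A), error = function(e) pinv_svd(A))
  mid <- crossprod(Delta, W %*% V %*% W %*% Delta)
  se <- sqrt(pmax(diag(Ainv %*% mid %*% Ainv), 0))

  browne_stat <- function(r, Delta) {
    Vi <- tryCatch(solve(V), error = function(e) pinv_svd(V))
    if (is.null(Delta) || ncol(Delta) == 0) return(drop(crossprod(r, Vi %*% r)))
    B <- crossprod(Delta, Vi %*% Delta)
    Bi <- tryCatch(solve(B), error = function(e) pinv_svd(B))
    U <- Vi - Vi %*% Delta %*% Bi %*% t(Delta) %*% Vi
    max(drop(crossprod(r, U %*% r)), 0)
  }

  df <- p_star - lay$q
  chi2 <- if (df > 0) browne_stat(r, Delta) else 0

  # independence model: free variances only
  diag_idx <- which(vech(diag(lay$k) == 1))
  r0 <- s
  r0[diag_idx] <- 0
  D0 <- matrix(0, p_star, lay$k)
  D0[cbind(diag_idx, seq_len(lay$k))] <- 1
  df0 <- p_star - lay$k
  chi0 <- browne_stat(r0, D0)

  cfi <- if (df == 0) 1 else {
    num <- max(chi2 - df, 0)
    den <- max(chi0 - df0, chi2 - df, 0)
    if (den == 0) 1 else 1 - num / den
  }
  # SRMR on correlation scale
  d <- sqrt(diag(S))
  Rres <- (S - cfa_implied(th, lay)) / tcrossprod(d)
  srmr <- sqrt(mean(Rres[lower.tri(Rres, diag = TRUE)]^2))

  ests <- data.frame(
    parameter = c(sprintf("%s=~%s", names(model_spec$factors)[lay$edges$factor],
                          lay$traits[lay$edges$trait]),
                  if (lay$ncorr > 0) {
                    cn <- utils::combn(names(model_spec$factors), 2)
                    sprintf("%s~~%s", cn[1, ], cn[2, ])
                  },
                  sprintf("%s~~%s", lay$traits, lay$traits)),
    estimate = th, se = se,
    z = th / se,
    p = 2 * stats::pnorm(-abs(th / se)),
    stringsAsFactors = FALSE)

  structure(list(estimates = ests, chi2 = chi2, df = df,
                 p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
                 aic = chi2 + 2 * lay$q,
                 cfi = min(max(cfi, 0), 1), srmr = srmr,
                 implied = cfa_implied(th, lay),
                 residuals = unvech(r),
                 spec = model_spec, layout = lay,
                 converged = opt$convergence %in% c(0, 1),
                 objective = opt$objective),
            class = "cfa_fit")
}

# svd pseudo-inverse fallback for near-singular information matrices
pinv_svd <- function(X, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("cfa_fit: chi2(%d) = %.2f, AIC = %.2f, CFI = %.3f, SRMR = %.3f\n",
              x$df, x$chi2, x$aic, x$cfi, x$srmr))
  print(x$estimates, digits = 3)
  invisible(x)
}
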