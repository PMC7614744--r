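#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()] with
#' enforced monotonicity, optionally against a declared grid size `m`
#' larger than the number of p-values supplied.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param m number of comparisons (default `length(p_values)`).
#' @return q-values, same length as `p_values`.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH", n = m)
}

marginal_r2 <- function(fit) {
  # Nakagawa & Schielzeth: fixed-effects variance over total
  if (inherits(fit, "lmerMod")) {
    fe <- stats::model.matrix(fit) %*% lme4::fixef(fit)
    vf <- stats::var(as.vector(fe))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vr <- sum(vc$vcov[vc$grp != "Residual"])
    ve <- vc$vcov[vc$grp == "Residual"]
    c(marginal = vf / (vf + vr + ve),
      conditional = (vf + vr) / (vf + vr + ve))
  } else {
    r2 <- summary(fit)$r.squared
    c(marginal = r2, conditional = r2)
  }
}

check_design <- function(df, cols) {
  X <- stats::model.matrix(~., df[, cols, drop = FALSE])
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
}

fit_pgs_model <- function(d, outcome, preds, site_col) {
  multi_site <- length(unique(d[[site_col]])) > 1
  rhs <- paste(preds, collapse = " + ")
  if (!length(preds)) rhs <- "1"
  if (multi_site) {
    fo <- stats::as.formula(paste(outcome, "~", rhs,
                                  "+ (1 |", site_col, ")"))
    suppressMessages(lme4::lmer(fo, data = d, REML = TRUE))
  } else {
    stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  }
}

wald_row <- function(fit, term) {
  co <- if (inherits(fit, "lmerMod")) summary(fit)$coefficients
        else summary(fit)$coefficients
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  z <- est / se
  c(beta = est, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Mixed-model association of a polygenic score with a phenotype
#'
#' Fits outcome ~ PGS + covariates with a site random intercept by REML
#' (plain least squares when only one site is present). Reports the
#' Wald p for the PGS term and the change in marginal R-squared
#' (fixed-effects variance over total variance) relative to the
#' covariate-only model; the conditional R-squared change is returned
#' alongside.
#'
#' @param pheno phenotype data.frame (one row per sample_id).
#' @param scores matrix or data.frame of scores, rownames sample ids.
#' @param outcome outcome column name in `pheno`.
#' @param predictor score column name in `scores`.
#' @param covariates covariate columns (default age, sex, PC1-PC5).
#' @param site_col site column name (default "site").
#' @return one-row data.frame (class `assoc_result`): outcome,
#'   predictor, beta, se, p, delta_r2, delta_r2_conditional, n.
#' @export
pgs_phenotype_regression <- function(pheno, scores, outcome, predictor,
                                     covariates = c("age", "sex",
                                                    paste0("PC", 1:5)),
                                     site_col = "site") {
  d <- merge_scores(pheno, scores, predictor)
  check_design(d, c(predictor, covariates))
  full <- fit_pgs_model(d, outcome, c(predictor, covariates), site_col)
  base <- fit_pgs_model(d, outcome, covariates, site_col)
  wr <- wald_row(full, predictor)
  r2f <- marginal_r2(full); r2b <- marginal_r2(base)
  out <- data.frame(outcome = outcome, predictor = predictor,
                    beta = wr[["beta"]], se = wr[["se"]], p = wr[["p"]],
                    delta_r2 = r2f[["marginal"]] - r2b[["marginal"]],
                    delta_r2_conditional = r2f[["conditional"]] -
                      r2b[["conditional"]],
                    n = nrow(d), stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

merge_scores <- function(pheno, scores, cols) {
  scores <- as.matrix(scores)
  idx <- match(pheno$sample_id, rownames(scores))
  if (anyNA(idx)) stop("samples missing from score matrix")
  d <- pheno
  for (cc in cols) d[[cc]] <- scores[idx, cc]
  d
}

#' Nested comparison: does an added PGS explain phenotype variance
#' beyond a base PGS?
#'
#' Fits covariates + base PGS, then adds the second score; reports the
#' added term's Wald p and the marginal R-squared increment.
#'
#' @inheritParams pgs_phenotype_regression
#' @param base_pgs,added_pgs score column names (must differ).
#' @return one-row data.frame: outcome, base, added, beta_added, se, p,
#'   delta_r2.
#' @export
nested_pgs_comparison <- function(pheno, scores, outcome, base_pgs,
                                  added_pgs,
                                  covariates = c("age", "sex",
                                                 paste0("PC", 1:5)),
                                  site_col = "site") {
  if (identical(base_pgs, added_pgs))
    stop("base_pgs and added_pgs must differ")
  d <- merge_scores(pheno, scores, c(base_pgs, added_pgs))
  base <- fit_pgs_model(d, outcome, c(base_pgs, covariates), site_col)
  full <- suppressWarnings(
    fit_pgs_model(d, outcome, c(base_pgs, added_pgs, covariates), site_col))
  co_names <- rownames(if (inherits(full, "lmerMod"))
    summary(full)$coefficients else summary(full)$coefficients)
  if (!added_pgs %in% co_names ||
      (inherits(full, "lm") && is.na(stats::coef(full)[added_pgs]))) {
    # added score is collinear with the base model: no incremental signal
    warning("added_pgs is collinear with the base model; zero increment")
    return(data.frame(outcome = outcome, base = base_pgs, added = added_pgs,
                      beta_added = 0, se = NA_real_, p = NA_real_,
                      delta_r2 = 0, stringsAsFactors = FALSE))
  }
  wr <- wald_row(full, added_pgs)
  data.frame(outcome = outcome, base = base_pgs, added = added_pgs,
             beta_added = wr[["beta"]], se = wr[["se"]], p = wr[["p"]],
             delta_r2 = marginal_r2(full)[["marginal"]] -
               marginal_r2(base)[["marginal"]],
             stringsAsFactors = FALSE)
}

#' Top-versus-bottom quintile odds ratio for clinical-range
#' psychopathology
#'
#' Restricts to the top and bottom PGS quintiles and fits a logistic
#' regression of the clinical flag on a top-quintile indicator plus
#' covariates; OR = exp(beta) with Wald 95% CI. Without covariates and
#' with a zero cell, the Haldane-Anscombe 0.5 correction is applied to
#' the 2x2 table (flagged). In `emergent` mode, individuals flagged at
#' baseline are excluded and the follow-up flag is the outcome.
#'
#' @param pheno phenotype data.frame containing the outcome flag.
#' @param quintiles integer vector/matrix column of quintile assignments
#'   (1-5), aligned to `pheno$sample_id`.
#' @param outcome_flag logical/0-1 column name in `pheno` (default
#'   "clinical").
#' @param covariates covariate columns (character(0) for the crude OR).
#' @param baseline_flag optional column; when given, rows with a TRUE
#'   baseline flag are dropped first (emergent mode).
#' @return one-row data.frame: or, ci_lo, ci_hi, p, n_top, n_bottom,
#'   corrected.
#' @export
quintile_logistic_or <- function(pheno, quintiles, outcome_flag = "clinical",
                                 covariates = character(0),
                                 baseline_flag = NULL) {
  d <- pheno
  d$quintile <- as.integer(quintiles)
  if (!is.null(baseline_flag)) d <- d[!as.logical(d[[baseline_flag]]), ]
  d <- d[d$quintile %in% c(1L, 5L), ]
  d$top <- as.integer(d$quintile == 5L)
  y <- as.integer(as.logical(d[[outcome_flag]]))
  corrected <- FALSE
  if (!length(covariates)) {
    tab <- table(factor(d$top, 0:1), factor(y, 0:1))
    if (any(tab == 0)) {
      tab <- tab + 0.5
      corrected <- TRUE
    }
    or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
    se <- sqrt(sum(1 / tab))
    beta <- log(or)
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    fo <- stats::as.formula(paste0("y ~ top + ",
                                   paste(covariates, collapse = " + ")))
    fit <- stats::glm(fo, data = cbind(d, y = y), family = stats::binomial())
    co <- summary(fit)$coefficients
    beta <- co["top", "Estimate"]; se <- co["top", "Std. Error"]
    or <- exp(beta)
    p <- co["top", "Pr(>|z|)"]
  }
  data.frame(or = or,
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = p, n_top = sum(d$top == 1), n_bottom = sum(d$top == 0),
             corrected = corrected, stringsAsFactors = FALSE)
}
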