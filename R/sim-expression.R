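#' Simulate a developmental brain expression atlas with planted timing
#' classes
#'
#' Emulates a region-resolved pre/postnatal expression atlas: each donor
#' contributes one sample per region; expression is generated on the
#' log2 scale as gene baseline + donor random intercept + planted
#' developmental shift + noise, then transformed to a non-negative
#' RPKM-like scale (2^y - 1, floored at 0). Per region, a fraction
#' `prop_prenatal` of genes gets a prenatal-peak shift of `expr_effect`
#' donor-level standard deviations, `prop_postnatal` the reverse, and
#' the remainder are flat ("continuous").
#'
#' @param config a [sim_config()].
#' @return list with `atlas` (an `expression_atlas`: `expr` genes x
#'   samples matrix, `samples` metadata with donor_id, region, age,
#'   prenatal) and `truth` (genes x regions class matrix).
#' @export
simulate_expression_atlas <- function(config) {
  if (config$n_donors_pre < 2 || config$n_donors_post < 2)
    stop("need at least 2 donors per developmental window")
  set.seed(config$seed + 3L)
  ng <- config$n_genes
  regions <- config$regions
  d_pre <- config$n_donors_pre
  d_post <- config$n_donors_post
  nd <- d_pre + d_post
  donors <- sprintf("donor%03d", seq_len(nd))
  prenatal <- c(rep(TRUE, d_pre), rep(FALSE, d_post))
  age <- c(stats::runif(d_pre, -0.7, -0.1), stats::runif(d_post, 0.5, 40))

  samples <- data.frame(
    sample_id = paste0(rep(donors, times = length(regions)), "_",
                       rep(regions, each = nd)),
    donor_id = rep(donors, times = length(regions)),
    region = rep(regions, each = nd),
    age = rep(age, times = length(regions)),
    prenatal = rep(prenatal, times = length(regions)),
    stringsAsFactors = FALSE)

  cls <- matrix(
    sample(c("prenatal", "postnatal", "continuous"), ng * length(regions),
           replace = TRUE,
           prob = c(config$prop_prenatal, config$prop_postnatal,
                    1 - config$prop_prenatal - config$prop_postnatal)),
    ng, length(regions), dimnames = list(sprintf("gene%04d", seq_len(ng)),
                                         regions))

  sd_donor <- 0.5
  sd_eps <- 1
  shift <- config$expr_effect * sqrt(sd_donor^2 + sd_eps^2)
  mu_g <- stats::rnorm(ng, 5, 1)
  u_donor <- stats::rnorm(nd, 0, sd_donor)

  Y <- matrix(0, ng, nrow(samples),
              dimnames = list(rownames(cls), samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    r <- samples$region[s]
    pre <- samples$prenatal[s]
    eff <- ifelse(cls[, r] == "prenatal", ifelse(pre, shift, 0),
                  ifelse(cls[, r] == "postnatal", ifelse(pre, 0, shift), 0))
    Y[, s] <- mu_g + u_donor[match(samples$donor_id[s], donors)] + eff +
      stats::rnorm(ng, 0, sd_eps)
  }
  expr <- pmax(2^Y - 1, 0)

  atlas <- structure(list(expr = expr, samples = samples),
                     class = "expression_atlas")
  list(atlas = atlas, truth = cls)
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("expression_atlas:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples;", length(unique(x$samples$donor_id)), "donors,",
      length(unique(x$samples$region)), "regions\n")
  invisible(x)
}

#' Write an expression atlas as matrix + metadata text files
#' @param atlas an `expression_atlas`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(atlas$expr, file.path(dir, "expression.tsv"),
                     quote = FALSE, sep = "\t", col.names = NA)
  utils::write.table(atlas$samples, file.path(dir, "samples.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(dir)
}

#' Read an expression atlas written by [write_atlas()]
#' @param dir directory containing expression.tsv and samples.tsv.
#' @return an `expression_atlas`.
#' @export
read_atlas <- function(dir) {
  expr <- as.matrix(utils::read.table(file.path(dir, "expression.tsv"),
                                      header = TRUE, sep = "\t",
                                      row.names = 1, check.names = FALSE))
  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  structure(list(expr = expr, samples = samples),
            class = "expression_atlas")
}
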