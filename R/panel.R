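#' Construct a genotype panel
#'
#' Container for an individuals x variants dosage matrix (counted allele =
#' a1; entries 0/1/2 or NA) with variant metadata. Positions are 1-based
#' and must be non-decreasing within chromosome; sample and variant ids
#' must be unique.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param variants data.frame with columns chrom, pos, id, a1, a2.
#' @param dosage numeric matrix, length(sample_ids) x nrow(variants).
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, variants, dosage) {
  sample_ids <- as.character(sample_ids)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "a1", "a2") %in% names(variants)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(variants$a1 == variants$a2)) stop("a1 must differ from a2")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome")
  }
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(variants))
    stop("dosage dimensions must be samples x variants")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(sample_ids, variants$id)
  structure(list(sample_ids = sample_ids,
                 variants = variants,
                 dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$dosage))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "),
      sprintf("; missingness %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Counted-allele (a1) frequency per variant
#' @param panel a `genotype_panel`.
#' @return numeric vector of a1 frequencies.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' Subset a genotype panel by samples and/or variants
#' @param panel a `genotype_panel`.
#' @param samples sample ids or indices to keep (default all).
#' @param variants variant ids or indices to keep (default all).
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(panel$sample_ids) else {
    if (is.character(samples)) match(samples, panel$sample_ids) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(panel$variants)) else {
    if (is.character(variants)) match(variants, panel$variants$id) else variants
  }
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown variant id in subset")
  out <- genotype_panel(panel$sample_ids[si],
                        panel$variants[vi, , drop = FALSE],
                        panel$dosage[si, vi, drop = FALSE])
  attr(out, "ld_blocks") <- attr(panel, "ld_blocks")[vi]
  out
}
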