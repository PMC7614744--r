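#' Windowed SNP-to-gene annotation
#'
#' Assigns SNPs to genes whose strand-aware window contains them: a
#' plus-strand gene (start, end) claims [start - up_kb, end + down_kb];
#' a minus-strand gene claims [start - down_kb, end + up_kb]. A SNP may
#' map to several genes. With `ignore_strand = TRUE` every gene uses the
#' plus-strand window.
#'
#' @param x a [sumstats()] object or a data.frame with chrom, pos, id.
#' @param gene_map a `gene_map` data.frame (1-based inclusive).
#' @param up_kb upstream window in kb (default 35).
#' @param down_kb downstream window in kb (default 10).
#' @param ignore_strand apply the plus-strand window to all genes.
#' @return object of class `snp_annotation`: data.frame `map` (snp_id,
#'   gene_id) plus accessors [snps_of_gene()] and [genes_of_snp()].
#' @export
annotate_snps_to_genes <- function(x, gene_map, up_kb = 35, down_kb = 10,
                                   ignore_strand = FALSE) {
  if (inherits(x, "genotype_panel")) x <- x$variants
  stopifnot(all(c("chrom", "pos", "id") %in% names(x)))
  if (!all(gene_map$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(setdiff(unique(gene_map$strand), c("+", "-")), collapse = ", "))
  up <- up_kb * 1000
  down <- down_kb * 1000
  plus <- gene_map$strand == "+" | ignore_strand
  wstart <- ifelse(plus, gene_map$start - up, gene_map$start - down)
  wend <- ifelse(plus, gene_map$end + down, gene_map$end + up)

  res <- list()
  for (ch in unique(gene_map$chrom)) {
    gi <- which(gene_map$chrom == ch)
    si <- which(x$chrom == ch)
    if (!length(gi) || !length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = x$pos[si], width = 1L),
      IRanges::IRanges(start = wstart[gi], end = wend[gi]))
    res[[ch]] <- data.frame(
      snp_id = x$id[si][S4Vectors::queryHits(hits)],
      gene_id = gene_map$gene_id[gi][S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  map <- if (length(res)) do.call(rbind, res) else
    data.frame(snp_id = character(0), gene_id = character(0))
  rownames(map) <- NULL
  structure(list(map = map, gene_map = gene_map,
                 up_kb = up_kb, down_kb = down_kb),
            class = "snp_annotation")
}

#' SNP ids annotated to a gene
#' @param annot a `snp_annotation`.
#' @param gene_id gene identifier(s).
#' @return character vector of SNP ids.
#' @export
snps_of_gene <- function(annot, gene_id) {
  unique(annot$map$snp_id[annot$map$gene_id %in% gene_id])
}

#' Gene ids a SNP is annotated to
#' @param annot a `snp_annotation`.
#' @param snp_id SNP identifier(s).
#' @return character vector of gene ids.
#' @export
genes_of_snp <- function(annot, snp_id) {
  unique(annot$map$gene_id[annot$map$snp_id %in% snp_id])
}

#' @export
print.snp_annotation <- function(x, ...) {
  cat("snp_annotation:", nrow(x$map), "assignments,",
      length(unique(x$map$snp_id)), "SNPs,",
      length(unique(x$map$gene_id)), "genes",
      sprintf("(window %g kb up / %g kb down)\n", x$up_kb, x$down_kb))
  invisible(x)
}
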