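#' Simulate a complete synthetic study
#'
#' Wires the generators together in pipeline order: genotypes, gene map,
#' eight-disorder summary statistics with the planted factor structure,
#' the developmental expression atlas, and the phenotype table whose
#' causal genetic effects live in the configured (region, timing class)
#' partition. The truth record accumulates everything recovery tests
#' need: per-SNP joint and factor-level effects, per-gene timing classes
#' per region, the causal SNP set, and the realized liability.
#'
#' @param config a [sim_config()].
#' @return list: panel, gene_map, sumstats (list of 8), atlas, pheno,
#'   truth.
#' @export
simulate_study <- function(config) {
  panel <- simulate_genotypes(config)
  gene_map <- simulate_gene_map(config, panel)
  ms <- simulate_multitrait_sumstats(config, panel)
  ea <- simulate_expression_atlas(config)
  truth <- ms$truth
  truth$gene_class <- ea$truth

  annot <- annotate_snps_to_genes(panel$variants, gene_map)
  region <- config$causal_partition[1]
  cls <- config$causal_partition[2]
  causal_genes <- rownames(ea$truth)[ea$truth[, region] == cls]
  truth$causal_genes <- causal_genes
  truth$causal_snps <- snps_of_gene(annot, causal_genes)

  pheno <- simulate_phenotypes(config, panel, truth)
  truth$liability <- attr(pheno, "liability")

  list(panel = panel, gene_map = gene_map, sumstats = ms$sumstats,
       atlas = ea$atlas, pheno = pheno, truth = truth, annot = annot,
       config = config)
}

#' Write every simulated input of a study to disk in standard formats
#'
#' PLINK bed/bim/fam genotypes, tab-delimited summary statistics per
#' disorder, BED-like gene map, atlas matrix + sample metadata, and the
#' phenotype table.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(study$panel, file.path(dir, "genotypes"))
  for (tr in names(study$sumstats))
    write_sumstats(study$sumstats[[tr]],
                   file.path(dir, paste0("sumstats_", tr, ".tsv")))
  write_gene_map(study$gene_map, file.path(dir, "genes.bed"))
  write_atlas(study$atlas, file.path(dir, "atlas"))
  write_phenotypes(study$pheno, file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}
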