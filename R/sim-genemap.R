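#' Simulate a non-overlapping gene map over a panel's coordinate range
#'
#' Tiles `n_genes` disjoint intervals across the panel's position range:
#' each gene occupies a jittered central portion of its slot, gets a
#' random strand and a unique id (`gene0001`, ... — the same scheme the
#' expression atlas uses, so gene identities line up across simulated
#' data sets). Coordinates are 1-based inclusive.
#'
#' @param config a [sim_config()].
#' @param panel a [genotype_panel()].
#' @return data.frame (class `gene_map`) with columns gene_id, chrom,
#'   start, end, strand.
#' @export
simulate_gene_map <- function(config, panel) {
  ng <- config$n_genes
  if (ng < 1) stop("n_genes must be >= 1")
  set.seed(config$seed + 2L)
  chroms <- unique(panel$variants$chrom)
  spans <- vapply(chroms, function(ch) {
    p <- panel$variants$pos[panel$variants$chrom == ch]
    diff(range(p)) + 1
  }, numeric(1))
  if (sum(spans) < 2 * ng)
    stop("coordinate range too small for ", ng, " disjoint genes")
  # allocate genes to chromosomes proportionally to span
  alloc <- floor(ng * spans / sum(spans))
  rem <- ng - sum(alloc)
  if (rem > 0) {
    extra <- order(spans, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  pieces <- list()
  for (i in seq_along(chroms)) {
    ngc <- alloc[i]
    if (ngc == 0) next
    p <- panel$variants$pos[panel$variants$chrom == chroms[i]]
    lo <- min(p)
    slot <- (diff(range(p)) + 1) / ngc
    starts <- floor(lo + (seq_len(ngc) - 1) * slot +
                      stats::runif(ngc, 0.05, 0.15) * slot)
    ends <- floor(lo + (seq_len(ngc) - 1) * slot +
                    stats::runif(ngc, 0.75, 0.95) * slot)
    pieces[[i]] <- data.frame(chrom = chroms[i],
                              start = as.integer(starts),
                              end = as.integer(pmax(ends, starts)),
                              stringsAsFactors = FALSE)
  }
  gm <- do.call(rbind, pieces)
  gm <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                   gm, strand = sample(c("+", "-"), ng, replace = TRUE),
                   stringsAsFactors = FALSE)
  class(gm) <- c("gene_map", "data.frame")
  gm
}

#' Write a gene map as 6-column BED-like text
#'
#' Disk format is BED-convention 0-based half-open (chrom, start, end,
#' name, score, strand); in memory the map is 1-based inclusive.
#' @param gm a `gene_map` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gm, path) {
  out <- data.frame(gm$chrom, gm$start - 1L, gm$end, gm$gene_id, ".",
                    gm$strand)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED-like gene map (0-based half-open on disk)
#' @param path input file.
#' @return a `gene_map` data.frame (1-based inclusive).
#' @export
read_gene_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = as.character(raw[[4]]),
                   chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]) + 1L,
                   end = as.integer(raw[[3]]),
                   strand = as.character(raw[[6]]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene ids")
  if (any(gm$start > gm$end)) stop("gene start > end")
  class(gm) <- c("gene_map", "data.frame")
  gm
}
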