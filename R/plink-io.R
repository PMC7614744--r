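#' Write a genotype panel as PLINK bed/bim/fam
#'
#' Emits the binary SNP-major .bed (magic bytes 0x6c 0x1b, mode 0x01) with
#' the standard 2-bit genotype codes, a .bim (chrom, id, 0 cM, pos, a1,
#' a2) and a .fam with placeholder pedigree fields. The counted dosage
#' allele a1 maps to the "first allele" column of the .bim.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix (files `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  m <- nrow(panel$variants)

  # 2-bit codes, individual-minor within byte: 00 hom a1, 10 het, 11 hom a2,
  # 01 missing (counting a1: 2, 1, 0, NA)
  code <- matrix(3L, n, max(m, 1L))
  if (m > 0) {
    D <- panel$dosage
    code[!is.na(D) & D == 2] <- 0L
    code[!is.na(D) & D == 1] <- 2L
    code[is.na(D)] <- 1L
  }
  npad <- ceiling(n / 4) * 4
  payload <- raw(0)
  if (m > 0) {
    cp <- matrix(0L, npad, m)
    cp[seq_len(n), ] <- code
    b1 <- cp[seq(1, npad, by = 4), , drop = FALSE]
    b2 <- cp[seq(2, npad, by = 4), , drop = FALSE]
    b3 <- cp[seq(3, npad, by = 4), , drop = FALSE]
    b4 <- cp[seq(4, npad, by = 4), , drop = FALSE]
    bytes <- b1 + 4L * b2 + 16L * b3 + 64L * b4
    payload <- as.raw(as.vector(bytes))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)

  bim <- data.frame(panel$variants$chrom, panel$variants$id,
                    rep(0L, m), panel$variants$pos,
                    panel$variants$a1, panel$variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype panel
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triplet.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bim <- tryCatch(
    utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                      colClasses = c("character", "character", "integer",
                                     "integer", "character", "character")),
    error = function(e) data.frame(V1 = character(0), V2 = character(0),
                                   V3 = integer(0), V4 = integer(0),
                                   V5 = character(0), V6 = character(0)))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw_all <- readBin(paste0(prefix, ".bed"), "raw",
                     n = file.size(paste0(prefix, ".bed")))
  if (length(raw_all) < 3 ||
      raw_all[1] != as.raw(0x6c) || raw_all[2] != as.raw(0x1b))
    stop("not a PLINK bed file: magic bytes mismatch")
  if (raw_all[3] != as.raw(0x01))
    stop("only SNP-major bed files (mode 0x01) are supported")
  payload <- raw_all[-(1:3)]
  bpv <- ceiling(n / 4)
  if (length(payload) != bpv * m)
    stop("bed payload size inconsistent with bim/fam row counts")

  D <- matrix(NA_real_, n, m)
  if (m > 0 && n > 0) {
    v <- as.integer(payload)
    dim(v) <- c(bpv, m)
    dos_of_code <- c(2, NA, 1, 0)  # codes 0,1,2,3
    for (shift in 0:3) {
      if (shift + 1 > n) break
      rows <- seq(shift + 1, n, by = 4)
      if (!length(rows)) next
      codes <- (v[ceiling(rows / 4), , drop = FALSE] %/% 4L^shift) %% 4L
      D[rows, ] <- dos_of_code[codes + 1L]
    }
  }
  variants <- bim[, c("chrom", "pos", "id", "a1", "a2")]
  genotype_panel(fam[[2]], variants, D)
}
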