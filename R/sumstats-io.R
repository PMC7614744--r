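#' Construct a summary-statistics table
#'
#' Validates the standard per-variant GWAS layout: chrom, pos, id, effect
#' allele a1, other allele a2, beta (log-OR for binary traits), se > 0,
#' p in (0, 1], n, optional info in [0, 1] and freq in (0, 1). When beta,
#' se and p are all present, |beta|/se is checked against the two-sided
#' normal p; inconsistencies beyond tolerance raise a warning (external
#' files often round p).
#'
#' @param df data.frame with the columns above.
#' @param check_z_tol tolerance on |z| implied by p (default 1e-6 on z).
#' @return object of class `sumstats` (a data.frame).
#' @export
sumstats <- function(df, check_z_tol = 1e-6) {
  req <- c("chrom", "pos", "id", "a1", "a2", "beta", "se", "p", "n")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required sumstats columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$se <= 0, na.rm = TRUE)) stop("se must be > 0")
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) stop("p must lie in (0, 1]")
  if (!is.null(df$info) && any(df$info < 0 | df$info > 1, na.rm = TRUE))
    stop("info must lie in [0, 1]")
  if (anyDuplicated(df$id)) stop("duplicate variant ids")
  ok <- !is.na(df$beta) & !is.na(df$se) & !is.na(df$p)
  if (any(ok)) {
    z_obs <- abs(df$beta[ok]) / df$se[ok]
    z_p <- stats::qnorm(pmax(df$p[ok], 1e-300) / 2, lower.tail = FALSE)
    bad <- abs(z_obs - z_p) > pmax(check_z_tol, 1e-4 * pmax(z_obs, 1))
    # p = 1 rows give z 0 with beta 0; p at the 1e-300 floor cannot match
    bad <- bad & df$p[ok] < 1 & df$p[ok] > 1e-290
    if (any(bad))
      warning(sum(bad), " rows have p inconsistent with |beta|/se")
  }
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Write summary statistics as tab-delimited text
#'
#' Header: CHR POS SNP A1 A2 BETA SE P N INFO FREQ.
#' @param ss a `sumstats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(CHR = ss$chrom, POS = ss$pos, SNP = ss$id,
                    A1 = ss$a1, A2 = ss$a2, BETA = ss$beta, SE = ss$se,
                    P = ss$p, N = ss$n,
                    INFO = ss$info %||% rep(1, nrow(ss)),
                    FREQ = ss$freq %||% rep(NA_real_, nrow(ss)))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

default_column_map <- function() {
  list(chrom = c("CHR", "CHROM", "#CHR", "CHROMOSOME"),
       pos = c("POS", "BP", "POSITION"),
       id = c("SNP", "ID", "RSID", "MARKERNAME"),
       a1 = c("A1", "EFFECT_ALLELE", "ALT", "EA"),
       a2 = c("A2", "OTHER_ALLELE", "REF", "OA", "NEA"),
       beta = c("BETA", "B", "EFFECT"),
       or = c("OR", "ODDS_RATIO"),
       se = c("SE", "STDERR", "STDERRLOGOR"),
       p = c("P", "PVAL", "P_VALUE", "PVALUE"),
       n = c("N", "NEFF", "N_TOTAL"),
       info = c("INFO", "IMPINFO"),
       freq = c("FREQ", "FRQ", "MAF", "A1FREQ", "EAF"))
}

#' Read GWAS summary statistics from tab-delimited text
#'
#' Column names are resolved case-insensitively through a synonym map
#' (BETA/OR, P/PVAL, ...). When only an OR column is present the effect is
#' converted to beta = ln(OR). Rows with unparseable numeric fields are
#' dropped and counted; duplicated variant ids keep the first occurrence
#' with a warning.
#'
#' @param path input file with header.
#' @param column_map optional named list of synonym vectors overriding the
#'   defaults (names: chrom, pos, id, a1, a2, beta, or, se, p, n, info, freq).
#' @return a [sumstats()] object; attribute `n_dropped` counts removed rows.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  cmap <- utils::modifyList(default_column_map(), column_map %||% list())
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  hdr <- toupper(names(raw))
  pick <- function(field) {
    hit <- match(toupper(cmap[[field]]), hdr)
    hit <- hit[!is.na(hit)]
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  beta <- num(pick("beta"))
  if (!length(beta)) {
    or <- num(pick("or"))
    if (!length(or)) stop("missing required column: BETA (or OR)")
    beta <- log(or)
  }
  df <- data.frame(chrom = as.character(pick("chrom") %||%
                     stop("missing required column: CHR")),
                   pos = num(pick("pos") %||%
                     stop("missing required column: POS")),
                   id = as.character(pick("id") %||%
                     stop("missing required column: SNP")),
                   a1 = toupper(pick("a1") %||%
                     stop("missing required column: A1")),
                   a2 = toupper(pick("a2") %||%
                     stop("missing required column: A2")),
                   beta = beta,
                   se = num(pick("se") %||%
                     stop("missing required column: SE")),
                   p = num(pick("p") %||%
                     stop("missing required column: P")),
                   n = num(pick("n") %||%
                     stop("missing required column: N")),
                   stringsAsFactors = FALSE)
  info <- num(pick("info")); freq <- num(pick("freq"))
  if (length(info)) df$info <- info
  if (length(freq)) df$freq <- freq

  ok <- stats::complete.cases(df[c("pos", "beta", "se", "p", "n")]) &
    df$se > 0 & df$p > 0 & df$p <= 1
  n_bad <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$id)
  if (any(dup)) {
    warning(sum(dup), " duplicated variant ids dropped (kept first occurrence)")
    df <- df[!dup, , drop = FALSE]
  }
  if (n_bad > 0)
    message(n_bad, " rows with unparseable or invalid numerics dropped")
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  out <- sumstats(df)
  attr(out, "n_dropped") <- n_bad + sum(dup)
  out
}
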