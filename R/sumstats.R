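# Canonical column roles for a summary-statistics table.
.sumstat_roles <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")
.numeric_roles <- c("pos", "eaf", "beta", "se", "pvalue", "n")

#' Read GWAS/eQTL summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file (optionally gzip-compressed) with a
#' header row and returns a validated summary-statistics data frame with the
#' canonical columns `snp`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n` (plus any extra columns named in
#' `column_map`, e.g. `gene` for eQTL input).
#'
#' Rows failing range validation (`se <= 0`, `eaf` outside (0,1), `pvalue`
#' outside (0,1], identical alleles, non-positive `n`) are removed from the
#' returned table and reported, with their line numbers, in the
#' `"invalid_rows"` attribute; a warning summarises the count. A missing
#' required column is a configuration error.
#'
#' @param path Path to the file. `.gz` input is decompressed transparently.
#' @param column_map Named character vector mapping file column names to
#'   roles, e.g. `c(SNP = "snp", EA = "effect_allele", ...)`. When `NULL`
#'   the file is assumed to already use the canonical role names.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `data.frame` of validated records, one per retained input row,
#'   with attribute `"invalid_rows"` describing rejected rows.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(snp = "rs1", chrom = "1", pos = 1000L,
#'              effect_allele = "A", other_allele = "G",
#'              eaf = 0.3, beta = 0.1, se = 0.02, pvalue = 5e-7, n = 20000L),
#'   f, sep = "\t", row.names = FALSE, quote = FALSE)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    hdr <- readLines(con, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(names(column_map), names(raw))
    if (length(missing_src))
      stop("column_map names columns absent from the file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    names(raw)[match(names(column_map), names(raw))] <- unname(column_map)
  }
  missing_roles <- setdiff(.sumstat_roles, names(raw))
  if (length(missing_roles))
    stop("summary-statistics input lacks required column(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  as_sumstats(raw, source = path)
}

#' Coerce and validate a summary-statistics data frame
#'
#' @param x A data frame carrying the canonical columns (see
#'   [read_sumstats()]); numeric columns may arrive as character.
#' @param source Label used in messages.
#' @return Validated data frame with an `"invalid_rows"` attribute.
#' @export
as_sumstats <- function(x, source = "sumstats") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_roles <- setdiff(.sumstat_roles, names(x))
  if (length(missing_roles))
    stop("missing required column(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  bad <- character(nrow(x))
  for (role in .numeric_roles) {
    v <- suppressWarnings(as.numeric(x[[role]]))
    unparse <- is.na(v) & !is.na(x[[role]]) & x[[role]] != "NA"
    bad[unparse] <- paste0(bad[unparse], role, " not numeric; ")
    x[[role]] <- v
  }
  x$snp <- as.character(x$snp)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  chk <- function(cond, msg) {
    hit <- !is.na(cond) & !cond
    bad[hit] <<- paste0(bad[hit], msg, "; ")
  }
  chk(x$se > 0, "se must be > 0")
  chk(x$eaf > 0 & x$eaf < 1, "eaf outside (0,1)")
  chk(x$pvalue > 0 & x$pvalue <= 1, "pvalue outside (0,1]")
  chk(x$n > 0, "n must be positive")
  chk(x$effect_allele != x$other_allele, "identical alleles")
  na_req <- !stats::complete.cases(x[.sumstat_roles])
  bad[na_req & bad == ""] <- "missing value in required column; "

  invalid <- which(bad != "")
  inv_df <- data.frame(line = invalid + 1L,          # +1 for the header row
                       snp = x$snp[invalid],
                       reason = sub("; $", "", bad[invalid]),
                       stringsAsFactors = FALSE)
  if (length(invalid)) {
    warning(sprintf("%s: %d row(s) failed validation and were dropped (see attr 'invalid_rows')",
                    source, length(invalid)), call. = FALSE)
    x <- x[-invalid, , drop = FALSE]
  }
  rownames(x) <- NULL
  structure(x, invalid_rows = inv_df, class = c("sumstats", "data.frame"))
}

#' Write summary statistics as tab-delimited text
#'
#' @param x Summary-statistics data frame.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  ok <- a1 %in% names(.complement) & a2 %in% names(.complement)
  ok & unname(.complement[a1]) == a2
}

new_exclusion_log <- function() {
  data.frame(snp = character(), stage = character(), detail = character(),
             stringsAsFactors = FALSE)
}

add_exclusion <- function(log, snp, stage, detail = "") {
  if (!length(snp)) return(log)
  rbind(log, data.frame(snp = snp, stage = stage, detail = detail,
                        stringsAsFactors = FALSE))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele, SNP by SNP.
#' When the outcome lists the same two alleles in swapped order, its beta is
#' negated and its EAF complemented. When the alleles only match after strand
#' complementation (an A/G vs T/C encoding), alleles are complemented before
#' comparison. Palindromic SNPs (A/T, C/G), whose strand cannot be resolved
#' from alleles alone, are removed when `drop_palindromic = TRUE` (the
#' default). SNPs absent from the outcome are excluded — no proxy lookup is
#' attempted — and allele sets irreconcilable by swap or strand flip are
#' excluded as mismatches.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [read_sumstats()]). Duplicate `snp` ids within either table are an
#'   error.
#' @param drop_palindromic Remove A/T and C/G SNPs (default `TRUE`).
#' @return A list with `pairs` (data frame with columns `snp`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `pval_exp`, `eaf_exp`, `n_exp`, `beta_out`, `se_out`, `pval_out`,
#'   `eaf_out`, `n_out`) and `exclusions` (snp, stage, detail). Every input
#'   exposure SNP appears exactly once in `pairs` or in `exclusions`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  for (nm in c("exposure", "outcome")) {
    d <- get(nm)
    dup <- unique(d$snp[duplicated(d$snp)])
    if (length(dup))
      stop("duplicated snp id(s) in ", nm, ": ",
           paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  log <- new_exclusion_log()

  idx <- match(exposure$snp, outcome$snp)
  miss <- is.na(idx)
  log <- add_exclusion(log, exposure$snp[miss], "missing_in_outcome",
                       "SNP absent from outcome; no proxy substitution")
  exp <- exposure[!miss, , drop = FALSE]
  out <- outcome[idx[!miss], , drop = FALSE]

  if (drop_palindromic) {
    pal <- .is_palindromic(exp$effect_allele, exp$other_allele)
    log <- add_exclusion(log, exp$snp[pal], "palindromic",
                         "A/T or C/G SNP removed")
    exp <- exp[!pal, , drop = FALSE]
    out <- out[!pal, , drop = FALSE]
  }

  oe <- out$effect_allele
  oo <- out$other_allele
  same <- oe == exp$effect_allele & oo == exp$other_allele
  swap <- oe == exp$other_allele & oo == exp$effect_allele
  # strand flip: complement outcome alleles, then compare again
  ce <- unname(.complement[oe]); ce[is.na(ce)] <- "?"
  co <- unname(.complement[oo]); co[is.na(co)] <- "?"
  flip_same <- !same & !swap & ce == exp$effect_allele & co == exp$other_allele
  flip_swap <- !same & !swap & ce == exp$other_allele & co == exp$effect_allele

  mismatch <- !(same | swap | flip_same | flip_swap)
  log <- add_exclusion(log, exp$snp[mismatch], "allele_mismatch",
                       paste0("exposure ", exp$effect_allele[mismatch], "/",
                              exp$other_allele[mismatch], " vs outcome ",
                              oe[mismatch], "/", oo[mismatch]))

  keep <- !mismatch
  exp <- exp[keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  flip_sign <- (swap | flip_swap)[keep]

  beta_out <- ifelse(flip_sign, -out$beta, out$beta)
  eaf_out <- ifelse(flip_sign, 1 - out$eaf, out$eaf)

  pairs <- data.frame(snp = exp$snp, chrom = exp$chrom, pos = exp$pos,
                      effect_allele = exp$effect_allele,
                      other_allele = exp$other_allele,
                      beta_exp = exp$beta, se_exp = exp$se,
                      pval_exp = exp$pvalue, eaf_exp = exp$eaf, n_exp = exp$n,
                      beta_out = beta_out, se_out = out$se,
                      pval_out = out$pvalue, eaf_out = eaf_out,
                      n_out = out$n, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, exclusions = log)
}

#' Convert harmonized pairs back into per-trait summary-statistic tables
#'
#' Utility used mainly for round-trip checks: splits a harmonized pair table
#' into exposure-side and outcome-side records expressed on the shared
#' effect allele.
#'
#' @param pairs Pair table from [harmonize()].
#' @return List with `exposure` and `outcome` summary-statistics frames.
#' @export
pairs_to_sumstats <- function(pairs) {
  base <- pairs[c("snp", "chrom", "pos", "effect_allele", "other_allele")]
  exposure <- cbind(base, data.frame(eaf = pairs$eaf_exp, beta = pairs$beta_exp,
                                     se = pairs$se_exp, pvalue = pairs$pval_exp,
                                     n = pairs$n_exp))
  outcome <- cbind(base, data.frame(eaf = pairs$eaf_out, beta = pairs$beta_out,
                                    se = pairs$se_out, pvalue = pairs$pval_out,
                                    n = pairs$n_out))
  list(exposure = as_sumstats(exposure), outcome = as_sumstats(outcome))
}

#' Write an exclusion log as TSV
#' @param log Exclusion log data frame (`snp`, `stage`, `detail`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(log, path) {
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
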