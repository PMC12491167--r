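#' Proportion of exposure variance explained by a SNP
#'
#' Computes, per SNP, \deqn{R^2 = \frac{2\,EAF(1-EAF)\beta^2}
#' {2\,EAF(1-EAF)\beta^2 + 2\,EAF(1-EAF)\,N\,SE^2},} which simplifies to
#' \eqn{\beta^2 / (\beta^2 + N\,SE^2)}; the allele-frequency factor cancels
#' but both forms are evaluated identically. Inputs are recycled.
#'
#' @param eaf Effect-allele frequency in (0,1).
#' @param beta Per-allele effect on the exposure.
#' @param se Standard error of `beta` (positive).
#' @param n Sample size (> 1).
#' @return Numeric vector of variance-explained values in [0,1).
#' @examples
#' variance_explained(0.5, 0.1, 0.01, 10000)  # 0.009901
#' @export
variance_explained <- function(eaf, beta, se, n) {
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0))
  if (any(n <= 1)) stop("sample size n must exceed 1", call. = FALSE)
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * n * se^2)
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}. Instruments with \eqn{F \le 10} are
#' conventionally considered weak.
#'
#' @param r2 Variance explained, in [0,1).
#' @param n Sample size (> 2).
#' @return F-statistic (non-negative).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0,1)", call. = FALSE)
  if (any(n <= 2)) stop("sample size n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Per-SNP instrument strength for a summary-statistics table
#' @param x Summary-statistics data frame (exposure trait).
#' @return Data frame with `snp`, `r2` and `f_stat`.
#' @export
instrument_strength <- function(x) {
  r2 <- variance_explained(x$eaf, x$beta, x$se, x$n)
  data.frame(snp = x$snp, r2 = r2, f_stat = f_statistic(r2, x$n),
             stringsAsFactors = FALSE)
}

#' Read pairwise LD (r-squared) information
#'
#' Accepts either a square matrix file (header row of SNP ids, first column
#' of SNP ids) or a three-column table `snp_a`, `snp_b`, `r2`; the pair list
#' is completed symmetrically and the diagonal set to 1.
#'
#' @param path Path to the LD file (TSV/CSV, optionally gzipped).
#' @return Symmetric numeric matrix with SNP ids as dimnames.
#' @export
read_ld <- function(path) {
  con <- gzfile(path, "rt")
  hdr <- readLines(con, n = 1L)
  close(con)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  fields <- strsplit(hdr, sep, fixed = TRUE)[[1]]
  if (length(fields) == 3 && tolower(fields[3]) %in% c("r2", "rsq", "r_2")) {
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    ld_from_pairs(d[[1]], d[[2]], d[[3]])
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                     row.names = 1, check.names = FALSE))
    if (nrow(m) != ncol(m)) stop("LD matrix is not square", call. = FALSE)
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
      stop("LD matrix is not symmetric", call. = FALSE)
    m
  }
}

#' Build a symmetric LD matrix from SNP pairs
#' @param snp_a,snp_b Character vectors of SNP ids.
#' @param r2 LD r-squared per pair.
#' @return Symmetric matrix over all mentioned SNPs (unlisted pairs 0,
#'   diagonal 1).
#' @export
ld_from_pairs <- function(snp_a, snp_b, r2) {
  ids <- sort(unique(c(snp_a, snp_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(snp_a, ids), match(snp_b, ids))] <- r2
  m[cbind(match(snp_b, ids), match(snp_a, ids))] <- r2
  diag(m) <- 1
  m
}

# r2 between two SNP id vectors; pairs absent from the matrix count as 0.
ld_lookup <- function(ld, a, b) {
  k <- max(length(a), length(b))
  if (is.null(ld)) return(rep(0, k))
  ia <- rep_len(match(a, rownames(ld)), k)
  ib <- rep_len(match(b, colnames(ld)), k)
  out <- rep(0, k)
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- ld[cbind(ia[ok], ib[ok])]
  out
}

#' Greedy LD clumping of exposure summary statistics
#'
#' Retains index SNPs by the standard greedy procedure: sort by exposure
#' p-value ascending (ties broken lexicographically by SNP id), keep the top
#' SNP, and drop every other SNP on the same chromosome within `window_kb`
#' kilobases whose r-squared with it is at least `r2_thresh`; repeat on the
#' remainder. SNP pairs absent from `ld` are treated as unlinked (r² = 0).
#'
#' @param x Summary-statistics (or harmonized-pair) data frame with `snp`,
#'   `chrom`, `pos` and a p-value column (`pvalue` or `pval_exp`).
#' @param ld LD matrix as from [read_ld()] / [simulate_ld()]; `NULL` means
#'   all SNPs unlinked.
#' @param r2_thresh Exclusion threshold on r² (default 0.01).
#' @param window_kb Half-window in kb around the index SNP (default 10000).
#' @return List with `retained` (subset of `x`, original order) and
#'   `exclusions` log (stage `ld_clump`).
#' @export
clump <- function(x, ld = NULL, r2_thresh = 0.01, window_kb = 10000) {
  stopifnot(r2_thresh > 0, r2_thresh < 1, window_kb > 0)
  p <- if ("pvalue" %in% names(x)) x$pvalue else x$pval_exp
  ord <- order(p, x$snp)
  queue <- x$snp[ord]
  chrom <- x$chrom[ord]
  pos <- x$pos[ord]
  keep <- character(0)
  dropped <- character(0)
  dropped_by <- character(0)
  active <- rep(TRUE, length(queue))
  for (i in seq_along(queue)) {
    if (!active[i]) next
    keep <- c(keep, queue[i])
    active[i] <- FALSE
    cand <- which(active & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window_kb * 1000)
    if (length(cand)) {
      r2 <- ld_lookup(ld, queue[i], queue[cand])
      hit <- cand[r2 >= r2_thresh]
      if (length(hit)) {
        dropped <- c(dropped, queue[hit])
        dropped_by <- c(dropped_by, rep(queue[i], length(hit)))
        active[hit] <- FALSE
      }
    }
  }
  log <- add_exclusion(new_exclusion_log(), dropped, "ld_clump",
                       if (length(dropped)) paste0("in LD with index SNP ", dropped_by) else character(0))
  list(retained = x[x$snp %in% keep, , drop = FALSE], exclusions = log)
}

#' Instrument-selection criteria
#'
#' Bundles the thresholds of the instrument-selection procedure: genome-wide
#' suggestive exposure association (p < 5e-6), LD pruning at r² < 0.01 in a
#' 10,000 kb window, minor-allele-frequency >= 0.01, an outcome-association
#' policy, and the weak-instrument cutoff F > 10.
#'
#' `outcome_p_policy` controls the outcome-association filter:
#' `"exclude_below"` (default) drops SNPs *associated* with the outcome
#' (p < `outcome_p`), guarding against confounded instruments;
#' `"exclude_above"` drops SNPs with outcome p above the threshold
#' (a literal reading of some published pipelines); `"off"` disables the
#' filter.
#'
#' @param p_exposure_max Exposure p-value threshold (keep p < this; 5e-6).
#' @param clump_r2 Clumping r² threshold (0.01).
#' @param clump_window_kb Clumping window, kb (10000).
#' @param maf_min Minimum minor allele frequency, `min(eaf, 1-eaf)` (0.01).
#' @param outcome_p_policy One of `"exclude_below"`, `"exclude_above"`,
#'   `"off"`.
#' @param outcome_p Outcome p-value threshold (0.05).
#' @param f_min Minimum F-statistic; SNPs with F <= `f_min` excluded (10).
#' @return A list of class `instrument_criteria`.
#' @export
instrument_criteria <- function(p_exposure_max = 5e-6, clump_r2 = 0.01,
                                clump_window_kb = 10000, maf_min = 0.01,
                                outcome_p_policy = c("exclude_below",
                                                     "exclude_above", "off"),
                                outcome_p = 0.05, f_min = 10) {
  outcome_p_policy <- match.arg(outcome_p_policy)
  stopifnot(p_exposure_max > 0, clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0, maf_min > 0, outcome_p > 0, f_min > 0)
  structure(list(p_exposure_max = p_exposure_max, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, maf_min = maf_min,
                 outcome_p_policy = outcome_p_policy, outcome_p = outcome_p,
                 f_min = f_min),
            class = "instrument_criteria")
}

#' Select instrumental variables from harmonized pairs
#'
#' Applies the selection filters in order: exposure p-value, minor allele
#' frequency, LD clumping, outcome-association policy, F-statistic. Each
#' excluded SNP is logged once with the first stage that removed it;
#' retained + excluded partitions the input.
#'
#' @param pairs Harmonized pair table from [harmonize()].
#' @param ld Optional LD matrix for clumping.
#' @param criteria An [instrument_criteria()] object.
#' @return List with `instruments` (pair subset), `exclusions` log, and
#'   `stage_counts` (named integer vector). When no SNP survives, an error
#'   of class `mr_no_instruments` is thrown carrying the stage counts in
#'   its `stage_counts` field.
#' @export
select_instruments <- function(pairs, ld = NULL,
                               criteria = instrument_criteria()) {
  stopifnot(inherits(criteria, "instrument_criteria"))
  log <- new_exclusion_log()
  cur <- pairs

  drop_stage <- function(cur, bad, stage, detail) {
    log <<- add_exclusion(log, cur$snp[bad], stage, detail)
    cur[!bad, , drop = FALSE]
  }
  cur <- drop_stage(cur, !(cur$pval_exp < criteria$p_exposure_max),
                    "p_exposure",
                    sprintf("exposure p >= %g", criteria$p_exposure_max))
  maf <- pmin(cur$eaf_exp, 1 - cur$eaf_exp)
  cur <- drop_stage(cur, maf < criteria$maf_min, "maf",
                    sprintf("MAF < %g", criteria$maf_min))
  cl <- clump(cur, ld, criteria$clump_r2, criteria$clump_window_kb)
  log <- rbind(log, cl$exclusions)
  cur <- cl$retained
  if (criteria$outcome_p_policy != "off") {
    bad <- if (criteria$outcome_p_policy == "exclude_below")
      cur$pval_out < criteria$outcome_p else cur$pval_out > criteria$outcome_p
    cur <- drop_stage(cur, bad, "outcome_p",
                      sprintf("outcome p %s %g",
                              if (criteria$outcome_p_policy == "exclude_below")
                                "<" else ">", criteria$outcome_p))
  }
  if (nrow(cur)) {
    r2 <- variance_explained(cur$eaf_exp, cur$beta_exp, cur$se_exp, cur$n_exp)
    f <- f_statistic(r2, cur$n_exp)
    cur <- drop_stage(cur, f <= criteria$f_min, "weak_instrument",
                      sprintf("F <= %g", criteria$f_min))
  }
  stages <- c("p_exposure", "maf", "ld_clump", "outcome_p", "weak_instrument")
  counts <- stats::setNames(vapply(stages, function(s) sum(log$stage == s),
                                   integer(1)), stages)
  if (!nrow(cur)) {
    e <- simpleError("no instruments survive selection")
    e$stage_counts <- counts
    class(e) <- c("mr_no_instruments", class(e))
    stop(e)
  }
  list(instruments = cur, exclusions = log, stage_counts = counts)
}
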