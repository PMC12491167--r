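# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# A minimal valid summary-statistics data frame.
make_records <- function(snp, beta, se, eaf = 0.3, pvalue = NULL,
                         n = 50000, chrom = "1", pos = NULL,
                         effect_allele = "A", other_allele = "G") {
  k <- length(snp)
  if (is.null(pos)) pos <- seq_len(k) * 1e6
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)),
                                      .Machine$double.xmin)
  as_sumstats(data.frame(
    snp = snp, chrom = rep_len(chrom, k), pos = pos,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    pvalue = pvalue, n = rep_len(n, k), stringsAsFactors = FALSE))
}

# A harmonized pair table built directly from effect vectors.
make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.05,
                       eaf = 0.3, n_exp = 50000, n_out = 60000,
                       snp = NULL, chrom = "1", pos = NULL) {
  k <- length(beta_exp)
  if (is.null(snp)) snp <- sprintf("rs%03d", seq_len(k))
  if (is.null(pos)) pos <- seq_len(k) * 1e6
  data.frame(snp = snp, chrom = rep_len(chrom, k), pos = pos,
             effect_allele = "A", other_allele = "G",
             beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
             pval_exp = pmax(2 * pnorm(-abs(beta_exp / rep_len(se_exp, k))),
                             .Machine$double.xmin),
             eaf_exp = rep_len(eaf, k), n_exp = rep_len(n_exp, k),
             beta_out = beta_out, se_out = rep_len(se_out, k),
             pval_out = pmax(2 * pnorm(-abs(beta_out / rep_len(se_out, k))),
                             .Machine$double.xmin),
             eaf_out = rep_len(eaf, k), n_out = rep_len(n_out, k),
             stringsAsFactors = FALSE)
}

# Independent greedy-clumping oracle: literal step-by-step simulation of
# the procedure (sort by p then id; keep top; drop linked in-window SNPs).
clump_oracle <- function(x, ld, r2_thresh, window_kb) {
  p <- if ("pvalue" %in% names(x)) x$pvalue else x$pval_exp
  d <- x[order(p, x$snp), c("snp", "chrom", "pos")]
  kept <- character(0)
  while (nrow(d)) {
    top <- d[1, ]
    kept <- c(kept, top$snp)
    d <- d[-1, , drop = FALSE]
    if (nrow(d)) {
      r2 <- vapply(d$snp, function(s) {
        if (s %in% rownames(ld) && top$snp %in% rownames(ld))
          ld[top$snp, s] else 0
      }, numeric(1))
      linked <- d$chrom == top$chrom &
        abs(d$pos - top$pos) <= window_kb * 1000 & r2 >= r2_thresh
      d <- d[!linked, , drop = FALSE]
    }
  }
  sort(kept)
}
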