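#' Summary-data-based MR (SMR) test for one gene
#'
#' Relates gene expression to an outcome through the gene's top cis-eQTL:
#' the effect of expression on outcome is estimated as
#' \eqn{b_{SMR} = \beta_{GWAS} / \beta_{eQTL}} at the top SNP, and tested
#' with \deqn{T_{SMR} = \frac{z_{GWAS}^2 z_{eQTL}^2}{z_{GWAS}^2 +
#' z_{eQTL}^2},} which follows a 1-df chi-square under the null. The
#' statistic is bounded by the smaller of the two squared z scores, so a
#' weak eQTL can never manufacture a significant SMR signal.
#' `se_smr = |b_smr| / sqrt(T_smr)`.
#'
#' @param beta_eqtl,se_eqtl Top-SNP effect on expression and its SE.
#' @param beta_gwas,se_gwas Top-SNP effect on the outcome and its SE.
#' @return List: `b_smr`, `se_smr`, `p_smr`, `t_smr`, `z_eqtl`, `z_gwas`.
#' @export
smr_test <- function(beta_eqtl, se_eqtl, beta_gwas, se_gwas) {
  stopifnot(se_eqtl > 0, se_gwas > 0)
  z_e <- beta_eqtl / se_eqtl
  z_g <- beta_gwas / se_gwas
  if (z_e == 0) stop("eQTL z-score is zero; SMR undefined", call. = FALSE)
  t_smr <- z_g^2 * z_e^2 / (z_g^2 + z_e^2)
  b_smr <- beta_gwas / beta_eqtl
  list(b_smr = b_smr,
       se_smr = if (t_smr > 0) abs(b_smr) / sqrt(t_smr) else Inf,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
       t_smr = t_smr, z_eqtl = z_e, z_gwas = z_g)
}

# Imhof's (1961) characteristic-function inversion for
# P(sum_i lambda_i X_i > q), X_i iid chi-square(1). Used for the HEIDI null.
.quadform_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10]
  if (!length(lambda)) return(1)
  if (q <= 0) return(1)
  if (length(lambda) == 1)       # exact single-component case
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  theta <- function(u)
    0.5 * vapply(u, function(ui) sum(atan(lambda * ui)), numeric(1)) - q * u / 2
  rho <- function(u)
    vapply(u, function(ui) exp(0.25 * sum(log1p(lambda^2 * ui^2))), numeric(1))
  f <- function(u) sin(theta(u)) / (u * rho(u))
  # split the oscillatory integral: a finite panel handled by adaptive
  # quadrature, plus the transformed tail
  split <- 100 / min(lambda)
  val <- tryCatch(
    stats::integrate(f, 0, split, subdivisions = 5000L,
                     rel.tol = 1e-10, stop.on.error = FALSE)$value +
      stats::integrate(f, split, Inf, subdivisions = 2000L,
                       rel.tol = 1e-8, stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (is.na(val)) {    # Satterthwaite two-moment fallback
    a <- sum(lambda^2) / sum(lambda)
    g <- sum(lambda)^2 / sum(lambda^2)
    return(stats::pchisq(q / a, g, lower.tail = FALSE))
  }
  min(max(0.5 + val / pi, 1e-300), 1)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (expression and outcome
#' association driven by one signal, in LD with every cis SNP) from
#' linkage of distinct causal variants. For each eligible cis SNP j,
#' \eqn{d_j = b_{SMR}(j) - b_{SMR}(top)}; under the single-variant null
#' all \eqn{d_j} are zero in expectation. The test statistic is the sum of
#' squared standardized differences; its null distribution, a weighted sum
#' of 1-df chi-squares with weights the eigenvalues of the correlation
#' matrix of d (delta-method covariance propagating both eQTL and GWAS
#' sampling error through the LD structure), is evaluated by numerical
#' characteristic-function inversion. A small HEIDI p-value indicates
#' heterogeneity, i.e. the association is better explained by linkage
#' than by a single causal variant.
#'
#' Eligible cis SNPs (excluding the top SNP itself) must pass the eQTL
#' p-value threshold and have LD r-squared with the top SNP inside
#' `r2_range`; the `max_snps` most significant are used. With fewer than
#' `min_snps` eligible SNPs the p-value is `NA` (undefined), with the
#' count reported.
#'
#' @param cis Data frame of cis SNPs with columns `snp`, `beta_eqtl`,
#'   `se_eqtl`, `beta_gwas`, `se_gwas`.
#' @param ld_r Signed LD correlation matrix (r, not r-squared) covering the
#'   cis SNPs; SNPs missing from it are dropped with a log entry.
#' @param min_snps,max_snps Bounds on the number of non-top SNPs used
#'   (defaults 3 and 20).
#' @param eqtl_p_max eQTL p-value ceiling for eligibility (default
#'   1.57e-3, i.e. chi-square(1) > 10).
#' @param r2_range Eligible LD r-squared with the top SNP (default
#'   [0.05, 0.9]; near-perfect LD makes d ill-conditioned, near-zero LD
#'   carries no linkage information).
#' @return List: `p_heidi` (`NA` when undefined), `n_used`, `top_snp`,
#'   `dropped` (SNPs without LD information).
#' @export
heidi_test <- function(cis, ld_r, min_snps = 3, max_snps = 20,
                       eqtl_p_max = 1.57e-3, r2_range = c(0.05, 0.9)) {
  stopifnot(nrow(cis) >= 1, all(cis$se_eqtl > 0), all(cis$se_gwas > 0))
  z_e <- cis$beta_eqtl / cis$se_eqtl
  p_e <- stats::pchisq(z_e^2, 1, lower.tail = FALSE)
  top <- which.min(p_e)

  in_ld <- cis$snp %in% rownames(ld_r)
  dropped <- cis$snp[!in_ld & seq_len(nrow(cis)) != top]
  if (!in_ld[top])
    stop("top SNP ", cis$snp[top], " absent from LD matrix", call. = FALSE)

  r_top <- ld_lookup(ld_r, cis$snp[top], cis$snp)
  eligible <- which(seq_len(nrow(cis)) != top & in_ld &
                      p_e < eqtl_p_max &
                      r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2])
  eligible <- eligible[order(p_e[eligible])]
  if (length(eligible) > max_snps) eligible <- eligible[seq_len(max_snps)]
  if (length(eligible) < min_snps)
    return(list(p_heidi = NA_real_, n_used = length(eligible),
                top_snp = cis$snp[top], dropped = dropped))

  idx <- c(top, eligible)          # position 1 = top
  bE <- cis$beta_eqtl[idx]
  sE <- cis$se_eqtl[idx]
  bG <- cis$beta_gwas[idx]
  sG <- cis$se_gwas[idx]
  b <- bG / bE
  R <- ld_r[cis$snp[idx], cis$snp[idx], drop = FALSE]

  # delta-method covariance of the per-SNP ratios (eQTL and GWAS samples
  # independent, so no cross terms)
  covb <- R * outer(sG, sG) / outer(bE, bE) +
    R * outer(b, b) * outer(sE, sE) / outer(bE, bE)
  m <- length(eligible)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ii <- i + 1L; jj <- j + 1L
    V[i, j] <- covb[ii, jj] - covb[ii, 1] - covb[jj, 1] + covb[1, 1]
  }
  d <- b[-1] - b[1]
  sd_d <- sqrt(diag(V))
  t_heidi <- sum((d / sd_d)^2)
  corr_d <- V / outer(sd_d, sd_d)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  list(p_heidi = .quadform_pvalue(t_heidi, lambda), n_used = m,
       top_snp = cis$snp[top], dropped = dropped)
}

#' Apply the SMR/HEIDI decision rule
#'
#' Flags genes with robust, potentially causal expression-outcome
#' associations: `p_smr < p_smr_max` (evidence of association) and
#' `p_heidi > p_heidi_min` (no evidence the association reflects linkage
#' rather than a shared causal variant). An undefined HEIDI p-value fails
#' the rule, with a reason recorded.
#'
#' @param results Data frame with columns `p_smr` and `p_heidi`.
#' @param p_smr_max SMR p-value ceiling (default 0.10).
#' @param p_heidi_min HEIDI p-value floor (default 0.05).
#' @return `results` with added logical `passes` and character `reason`.
#' @export
apply_decision_rule <- function(results, p_smr_max = 0.10,
                                p_heidi_min = 0.05) {
  smr_ok <- !is.na(results$p_smr) & results$p_smr < p_smr_max
  heidi_def <- !is.na(results$p_heidi)
  heidi_ok <- heidi_def & results$p_heidi > p_heidi_min
  results$passes <- smr_ok & heidi_ok
  results$reason <- ifelse(!smr_ok, sprintf("p_smr >= %g", p_smr_max),
                    ifelse(!heidi_def, "HEIDI undefined (too few eligible SNPs)",
                    ifelse(!heidi_ok, sprintf("p_heidi <= %g", p_heidi_min),
                           "passes")))
  results
}

#' SMR + HEIDI analysis across genes
#'
#' For each gene in an eQTL summary-statistics table (canonical columns
#' plus `gene`), harmonizes the cis SNPs against the outcome GWAS, takes
#' the most significant eQTL as the top instrument, and runs [smr_test()]
#' and [heidi_test()], then applies the decision rule.
#'
#' @param eqtl eQTL summary statistics with a `gene` column.
#' @param gwas Outcome GWAS summary statistics.
#' @param ld_r Signed LD correlation matrix over the cis SNPs.
#' @param ... Passed to [heidi_test()].
#' @param p_smr_max,p_heidi_min Decision-rule thresholds.
#' @return Data frame, one row per gene: `gene`, `top_snp`, `b_smr`,
#'   `se_smr`, `p_smr`, `or_smr`, `ci_low`, `ci_high`, `p_heidi`,
#'   `n_heidi_snps`, `passes`, `reason`.
#' @export
run_smr <- function(eqtl, gwas, ld_r, ..., p_smr_max = 0.10,
                    p_heidi_min = 0.05) {
  stopifnot("gene" %in% names(eqtl))
  rows <- lapply(split(seq_len(nrow(eqtl)), eqtl$gene), function(ix) {
    g <- eqtl[ix, , drop = FALSE]
    h <- harmonize(g, gwas, drop_palindromic = TRUE)
    pr <- h$pairs
    if (!nrow(pr)) return(NULL)
    cis <- data.frame(snp = pr$snp, beta_eqtl = pr$beta_exp,
                      se_eqtl = pr$se_exp, beta_gwas = pr$beta_out,
                      se_gwas = pr$se_out, stringsAsFactors = FALSE)
    topi <- which.min(pr$pval_exp)
    s <- smr_test(cis$beta_eqtl[topi], cis$se_eqtl[topi],
                  cis$beta_gwas[topi], cis$se_gwas[topi])
    hd <- heidi_test(cis, ld_r, ...)
    z <- stats::qnorm(0.975)
    data.frame(gene = g$gene[1], top_snp = cis$snp[topi],
               b_smr = s$b_smr, se_smr = s$se_smr, p_smr = s$p_smr,
               or_smr = exp(s$b_smr),
               ci_low = exp(s$b_smr - z * s$se_smr),
               ci_high = exp(s$b_smr + z * s$se_smr),
               p_heidi = hd$p_heidi, n_heidi_snps = hd$n_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  apply_decision_rule(out, p_smr_max, p_heidi_min)
}
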