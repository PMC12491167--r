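#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - \hat\beta)^2} over the per-SNP Wald
#' ratios, with IVW weights \eqn{w_j = \beta_{exp,j}^2 / se_{out,j}^2} and
#' \eqn{\hat\beta} the reference causal estimate (IVW, df = n - 1, or
#' MR-Egger fitted values, df = n - 2). Significant Q (p < 0.05) indicates
#' heterogeneity across instruments.
#'
#' @param pairs Harmonized pair table (>= 2 rows for IVW reference, >= 3
#'   for Egger).
#' @param reference `"ivw"` (default) or `"egger"`.
#' @return List of class `heterogeneity_result`: `q_stat`, `df`, `pvalue`.
#' @export
cochran_q <- function(pairs, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  .check_min_snps(pairs, if (reference == "ivw") 2L else 3L,
                  paste("Cochran's Q,", reference, "reference"))
  w <- 1 / pairs$se_out^2
  n <- nrow(pairs)
  if (reference == "ivw") {
    b <- mr_ivw(pairs, "fixed")$beta
    q <- sum(w * (pairs$beta_out - b * pairs$beta_exp)^2)
    df <- n - 1L
  } else {
    e <- mr_egger(pairs)
    flip <- sign(pairs$beta_exp)
    flip[flip == 0] <- 1
    resid <- pairs$beta_out * flip -
      (e$extra$intercept + e$beta * abs(pairs$beta_exp))
    q <- sum(w * resid^2)
    df <- n - 2L
  }
  structure(list(q_stat = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect n times, each time excluding one
#' instrument, to expose estimates driven by a single SNP.
#'
#' @param pairs Harmonized pair table (>= 3 rows).
#' @param estimator Function mapping a pair table to an `mr_estimate`
#'   (default IVW).
#' @return Data frame with one row per excluded SNP: `excluded_snp`,
#'   `beta`, `se`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(pairs, estimator = mr_ivw) {
  .check_min_snps(pairs, 3L, "leave-one-out")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- estimator(pairs[-i, , drop = FALSE])
    data.frame(excluded_snp = pairs$snp[i], beta = est$beta, se = est$se,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MR-Steiger directionality test
#'
#' Compares the exposure variance explained by the instrument set with the
#' outcome variance it explains. A causal exposure -> outcome orientation
#' predicts the instruments explain more variance in the exposure.
#' The p-value comes from a z-test on the difference of Fisher-transformed
#' instrument-trait correlations (`atanh(sqrt(r2))`) at the two sample
#' sizes. Ties (equal r2) are reported as `correct_direction = FALSE` with
#' p = 1, never as evidence of reverse causation.
#'
#' @param pairs Harmonized pair table with `n_exp` and `n_out` present.
#' @return List of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_direction`, `pvalue`.
#' @export
mr_steiger <- function(pairs) {
  .check_min_snps(pairs, 1L, "Steiger test")
  if (any(is.na(pairs$n_exp)) || any(is.na(pairs$n_out)))
    stop("Steiger test requires per-SNP sample sizes for both traits",
         call. = FALSE)
  r2_exp <- sum(variance_explained(pairs$eaf_exp, pairs$beta_exp,
                                   pairs$se_exp, pairs$n_exp))
  eaf_out <- if ("eaf_out" %in% names(pairs)) pairs$eaf_out else pairs$eaf_exp
  r2_out <- sum(variance_explained(eaf_out, pairs$beta_out,
                                   pairs$se_out, pairs$n_out))
  n_exp <- mean(pairs$n_exp)
  n_out <- mean(pairs$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 correct_direction = r2_exp > r2_out,
                 pvalue = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' Analytic power for a binary-outcome MR analysis
#'
#' Non-centrality-based normal approximation: the IVW z statistic has
#' approximate non-centrality
#' \eqn{\sqrt{n\,R^2\,\phi(1-\phi)}\,|\log OR|} for outcome sample size n,
#' case fraction \eqn{\phi} and instrument variance explained \eqn{R^2}, so
#' \deqn{power = \Phi(ncp - z_{1-\alpha/2}) + \Phi(-ncp - z_{1-\alpha/2}).}
#' At OR = 1 this reduces to \eqn{\alpha}. Exposures with power below 0.5
#' against a plausible alternative are poor candidates for causal
#' inference.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Fraction of cases among the outcome samples, (0,1).
#' @param r2_exposure Total exposure variance explained by the instruments.
#' @param or_alternative Odds ratio under the alternative hypothesis.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in [0,1].
#' @export
mr_power <- function(n_outcome, case_fraction, r2_exposure, or_alternative,
                     alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  stopifnot(n_outcome > 0, case_fraction > 0, case_fraction < 1,
            r2_exposure >= 0, r2_exposure < 1, or_alternative > 0)
  ncp <- sqrt(n_outcome * r2_exposure * case_fraction * (1 - case_fraction)) *
    abs(log(or_alternative))
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - zc) + stats::pnorm(-ncp - zc)
}

#' One-object sensitivity report for an instrument set
#'
#' Bundles the diagnostics that accompany each MR analysis: Cochran's Q
#' (IVW reference), the MR-Egger intercept test (from [mr_egger()]),
#' Steiger directionality, and, when the power inputs are supplied,
#' analytic power.
#'
#' @param pairs Harmonized pair table.
#' @param case_fraction,or_alternative Optional inputs for [mr_power()];
#'   power is `NA` when either is missing.
#' @param alpha Significance level for the power computation.
#' @return One-row data frame: `n_snp`, `q_stat`, `q_df`, `q_p`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `steiger_r2_exposure`, `steiger_r2_outcome`, `steiger_direction`,
#'   `steiger_p`, `power`.
#' @export
sensitivity_report <- function(pairs, case_fraction = NULL,
                               or_alternative = NULL, alpha = 0.05) {
  n <- nrow(pairs)
  q <- if (n >= 2) cochran_q(pairs, "ivw") else
    list(q_stat = NA_real_, df = NA_integer_, pvalue = NA_real_)
  eg <- if (n >= 3) mr_egger(pairs)$extra else
    list(intercept = NA_real_, intercept_se = NA_real_, intercept_p = NA_real_)
  st <- mr_steiger(pairs)
  power <- NA_real_
  if (!is.null(case_fraction) && !is.null(or_alternative))
    power <- mr_power(mean(pairs$n_out), case_fraction, st$r2_exposure,
                      or_alternative, alpha)
  data.frame(n_snp = n, q_stat = q$q_stat, q_df = q$df, q_p = q$pvalue,
             egger_intercept = eg$intercept,
             egger_intercept_se = eg$intercept_se,
             egger_intercept_p = eg$intercept_p,
             steiger_r2_exposure = st$r2_exposure,
             steiger_r2_outcome = st$r2_outcome,
             steiger_direction = st$correct_direction,
             steiger_p = st$pvalue, power = power,
             stringsAsFactors = FALSE)
}
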