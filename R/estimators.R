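# Per-SNP Wald ratios and their first-order variances; the workhorse inputs
# for the median- and mode-based estimators.
.ratios <- function(pairs) {
  list(ratio = pairs$beta_out / pairs$beta_exp,
       var = pairs$se_out^2 / pairs$beta_exp^2)
}

new_mr_estimate <- function(method, beta, se, pvalue, n_snp, extra = list()) {
  stopifnot(se >= 0)
  pvalue <- max(pvalue, .Machine$double.xmin)   # keep p in (0,1]
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or_ = exp(beta),
                 ci_low = exp(beta - stats::qnorm(0.975) * se),
                 ci_high = exp(beta + stats::qnorm(0.975) * se),
                 n_snp = n_snp, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pvalue))
  if (length(x$extra))
    cat("  extra:", paste(names(x$extra), signif(unlist(x$extra), 4),
                          sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, pvalue = x$pvalue,
             or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             n_snp = x$n_snp, stringsAsFactors = FALSE)
}

.check_min_snps <- function(pairs, k, method) {
  if (nrow(pairs) < k) {
    e <- simpleError(sprintf("%s requires at least %d instruments, got %d",
                             method, k, nrow(pairs)))
    class(e) <- c("mr_insufficient_instruments", class(e))
    stop(e)
  }
}

#' Wald ratio causal estimate from a single instrument
#'
#' The causal effect is the SNP-outcome effect divided by the SNP-exposure
#' effect; the default standard error is the first-order delta-method value
#' `se_out / |beta_exp|` (second-order, which also propagates the exposure
#' effect's uncertainty, available via `second_order = TRUE`).
#'
#' @param pairs Harmonized pair table with exactly one row (extra rows are
#'   an error; use [mr_ivw()] for several).
#' @param second_order Use the second-order delta-method standard error.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(pairs, second_order = FALSE) {
  if (nrow(pairs) != 1)
    stop("mr_wald_ratio expects exactly one instrument", call. = FALSE)
  if (pairs$beta_exp == 0)
    stop("beta_exp is zero; Wald ratio undefined", call. = FALSE)
  b <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  if (second_order)
    se <- sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
                 pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("wald", b, se, p, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`. Under the default multiplicative
#' random-effects model the standard error is inflated by
#' `max(1, sqrt(Q/(n-1)))`, so it never falls below the fixed-effects value;
#' `effects_model = "fixed"` reports the fixed-effects standard error.
#'
#' @param pairs Harmonized pair table (>= 1 row; one row reduces to the
#'   Wald ratio).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with `extra$q_stat` (heterogeneity about the
#'   IVW fit) when n >= 2.
#' @export
mr_ivw <- function(pairs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  .check_min_snps(pairs, 1L, "IVW")
  w <- 1 / pairs$se_out^2
  bx <- pairs$beta_exp
  by <- pairs$beta_out
  b <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  n <- nrow(pairs)
  q <- sum(w * (by - b * bx)^2)
  se <- se_fixed
  if (effects_model == "multiplicative_random" && n > 1)
    se <- se_fixed * max(1, sqrt(q / (n - 1)))
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("ivw", b, se, p, n,
                  extra = list(q_stat = q, effects_model = effects_model))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept (weights `1/se_out^2`), after orienting every instrument so
#' its exposure effect is non-negative. The intercept estimates the average
#' directional pleiotropy; an intercept indistinguishable from zero
#' supports instrument validity. Standard errors use the multiplicative
#' random-effects convention (residual dispersion floored at 1); p-values
#' come from the t distribution with n - 2 degrees of freedom.
#'
#' @param pairs Harmonized pair table (>= 3 rows).
#' @return An `mr_estimate` with `extra` fields `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(pairs) {
  .check_min_snps(pairs, 3L, "MR-Egger")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  bx <- abs(pairs$beta_exp)
  by <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # unit-weight coefficient SEs scaled by dispersion floored at 1, so the
  # standard error never falls below its fixed-effects value
  se_unit <- sqrt(diag(sm$cov.unscaled))
  infl <- max(1, sm$sigma)
  n <- nrow(pairs)
  b <- stats::coef(fit)[["bx"]]
  se <- se_unit[["bx"]] * infl
  a <- stats::coef(fit)[["(Intercept)"]]
  a_se <- se_unit[["(Intercept)"]] * infl
  new_mr_estimate("egger", b, se, 2 * stats::pt(-abs(b / se), n - 2), n,
                  extra = list(intercept = a, intercept_se = a_se,
                               intercept_p = 2 * stats::pt(-abs(a / a_se), n - 2)))
}

# Weighted median of values `b` with weights `w`: linear interpolation of
# the cumulative weight function (midpoint convention) at probability 0.5.
.weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(b[1])
  if (cw[length(cw)] <= 0.5) return(b[length(b)])
  i <- max(which(cw < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
}

# Parametric bootstrap SE: resample per-SNP effects from their sampling
# distributions and recompute the point estimate.
.boot_se <- function(pairs, estimator, n_boot, seed) {
  if (is.null(seed)) stop("a bootstrap seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- nrow(pairs)
  est <- vapply(seq_len(n_boot), function(i) {
    bp <- pairs
    bp$beta_exp <- stats::rnorm(n, pairs$beta_exp, pairs$se_exp)
    bp$beta_out <- stats::rnorm(n, pairs$beta_out, pairs$se_out)
    estimator(bp)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, with weights equal to
#' the inverse first-order variance of each ratio; consistent when at least
#' half of the instrument weight comes from valid instruments. The standard
#' error is obtained by parametric bootstrap.
#'
#' @param pairs Harmonized pair table (>= 3 rows).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed (required; no silent nondeterminism).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed) {
  .check_min_snps(pairs, 3L, "weighted median")
  r <- .ratios(pairs)
  b <- .weighted_median(r$ratio, 1 / r$var)
  se <- .boot_se(pairs, function(bp) {
    rb <- .ratios(bp)
    .weighted_median(rb$ratio, 1 / rb$var)
  }, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("weighted_median", b, se, p, nrow(pairs))
}

# Mode of the kernel-smoothed ratio distribution. Bandwidth: the modified
# Silverman rule 0.9 * min(sd, mad) * n^(-1/5), scaled by bandwidth_factor.
.kde_mode <- function(b, w, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(b), stats::mad(b)) / length(b)^(1 / 5)
  h <- max(1e-8, bandwidth_factor * s)
  d <- stats::density(b, weights = w / sum(w), bw = h, n = 2048)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimate (weighted or simple)
#'
#' The mode of the kernel-smoothed empirical density of the per-SNP Wald
#' ratios: the causal effect of the largest cluster of instruments with
#' similar ratios. The weighted variant weights each ratio by its inverse
#' variance; the simple variant weights all ratios equally. Standard error
#' by parametric bootstrap.
#'
#' @param pairs Harmonized pair table (>= 3 rows).
#' @param weighted Use inverse-variance weights (default `TRUE`).
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth
#'   (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed (required).
#' @return An `mr_estimate` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(pairs, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed) {
  .check_min_snps(pairs, 3L, "mode estimator")
  stopifnot(bandwidth_factor > 0)
  wfun <- function(rat) if (weighted) 1 / rat$var else rep(1, length(rat$ratio))
  r <- .ratios(pairs)
  b <- .kde_mode(r$ratio, wfun(r), bandwidth_factor)
  se <- .boot_se(pairs, function(bp) {
    rb <- .ratios(bp)
    .kde_mode(rb$ratio, wfun(rb), bandwidth_factor)
  }, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  b, se, p, nrow(pairs))
}

#' Run all applicable MR estimators on an instrument set
#'
#' With a single instrument only the Wald ratio is computed; with two,
#' IVW; with three or more, IVW, MR-Egger, weighted median, weighted mode
#' and simple mode.
#'
#' @param pairs Harmonized pair table.
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param seed Bootstrap seed (required when n >= 3).
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @return Data frame with one row per estimator: method, beta, se,
#'   pvalue, or_, ci_low, ci_high, n_snp.
#' @export
mr_all <- function(pairs, n_boot = 1000, seed = NULL,
                   effects_model = "multiplicative_random") {
  n <- nrow(pairs)
  ests <- if (n == 1) {
    list(mr_wald_ratio(pairs))
  } else if (n == 2) {
    list(mr_ivw(pairs, effects_model))
  } else {
    list(mr_ivw(pairs, effects_model),
         mr_egger(pairs),
         mr_weighted_median(pairs, n_boot, seed),
         mr_mode(pairs, weighted = TRUE, n_boot = n_boot, seed = seed),
         mr_mode(pairs, weighted = FALSE, n_boot = n_boot, seed = seed))
  }
  do.call(rbind, lapply(ests, as.data.frame))
}
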