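#' Two-step MR mediation decomposition
#'
#' Decomposes a total causal effect into mediated and direct components by
#' the product-of-coefficients method. With `beta1` the exposure->mediator
#' effect, `beta2` the mediator->outcome effect, and `beta3` the total
#' exposure->outcome effect (all on the log-odds scale for binary traits):
#' mediation effect = `beta1 * beta2`; direct effect =
#' `beta3 - beta1 * beta2`; proportion mediated =
#' `(beta1 * beta2) / beta3`. Additivity (direct + mediation = total) holds
#' exactly by construction.
#'
#' A mediated effect whose sign opposes the total effect is arithmetically
#' valid but not interpretable as partial mediation; such results carry
#' `consistent = FALSE` and should be reported as "no mediation" rather
#' than with a (negative or >100\%) proportion. The flag never alters the
#' numbers.
#'
#' When an upstream estimate is available only as an odds ratio, take
#' `beta1 = log(OR)` before calling.
#'
#' @param beta1 Exposure -> mediator effect.
#' @param beta2 Mediator -> outcome effect.
#' @param beta3 Total exposure -> outcome effect. When `beta3 = 0` the
#'   proportion is `NA` (undefined), the other quantities are still
#'   returned.
#' @param se1,se2 Optional standard errors of `beta1`, `beta2`; when both
#'   given, `se_mediation` is the first-order delta-method standard error
#'   of the product.
#' @return List of class `mediation_result`: `beta1`, `beta2`, `beta3`,
#'   `mediation_effect`, `direct_effect`, `proportion`, `consistent`,
#'   `se_mediation`.
#' @examples
#' two_step_mediation(log(1.279), -0.107, -0.693)
#' @export
two_step_mediation <- function(beta1, beta2, beta3, se1 = NULL, se2 = NULL) {
  stopifnot(is.numeric(beta1), is.numeric(beta2), is.numeric(beta3))
  med <- beta1 * beta2
  direct <- beta3 - med
  proportion <- if (beta3 == 0) NA_real_ else med / beta3
  se_med <- if (!is.null(se1) && !is.null(se2))
    mediation_se_delta(beta1, se1, beta2, se2) else NA_real_
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 mediation_effect = med, direct_effect = direct,
                 proportion = proportion,
                 consistent = !is.na(proportion) && sign(med) == sign(beta3),
                 se_mediation = se_med),
            class = "mediation_result")
}

#' Delta-method standard error of a product of two estimates
#'
#' First-order approximation for independent estimates:
#' `sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)`.
#'
#' @param beta1,se1 First estimate and its standard error.
#' @param beta2,se2 Second estimate and its standard error.
#' @return Standard error of `beta1 * beta2`.
#' @export
mediation_se_delta <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 >= 0, se2 >= 0)
  sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation decomposition\n")
  cat(sprintf("  beta1 (exposure->mediator) = %.4f\n", x$beta1))
  cat(sprintf("  beta2 (mediator->outcome)  = %.4f\n", x$beta2))
  cat(sprintf("  total effect  (beta3)      = %.4f\n", x$beta3))
  cat(sprintf("  mediation effect           = %.4f\n", x$mediation_effect))
  cat(sprintf("  direct effect              = %.4f\n", x$direct_effect))
  cat(sprintf("  proportion mediated        = %s\n",
              format_proportion(x$proportion)))
  if (!x$consistent)
    cat("  [mediation and total effects have opposing signs: no mediation reported]\n")
  invisible(x)
}

#' Format a mediated proportion as a percentage
#' @param p Proportion (fraction); `NA` allowed.
#' @param digits Decimal places (default 3, e.g. "3.800\%").
#' @return Character scalar.
#' @export
format_proportion <- function(p, digits = 3) {
  if (is.na(p)) return("undefined")
  paste0(formatC(100 * p, format = "f", digits = digits), "%")
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(beta1 = x$beta1, beta2 = x$beta2, total_effect = x$beta3,
             direct_effect = x$direct_effect,
             mediation_effect = x$mediation_effect,
             proportion = x$proportion,
             proportion_pct = ifelse(is.na(x$proportion), NA_character_,
                                     format_proportion(x$proportion)),
             consistent = x$consistent, se_mediation = x$se_mediation,
             stringsAsFactors = FALSE)
}
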