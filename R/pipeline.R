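#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs (every p in (0,1]) and returns BH-adjusted
#' p-values in the input order: adjusted_i = min over j >= i (by sorted
#' rank) of p_j * m / j, capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values in (0,1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0,1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Dual significance rule
#'
#' An association is flagged significant iff its raw p-value is below
#' `alpha_raw` (default 0.05) and its BH-adjusted p-value is below
#' `alpha_adjusted` (default 0.10).
#'
#' @param p Raw p-values.
#' @param p_adjusted BH-adjusted p-values.
#' @param alpha_raw,alpha_adjusted Thresholds.
#' @return Logical vector.
#' @export
flag_significant <- function(p, p_adjusted, alpha_raw = 0.05,
                             alpha_adjusted = 0.10) {
  p < alpha_raw & p_adjusted < alpha_adjusted
}

#' Two-sample MR analysis of one exposure-outcome pair
#'
#' End-to-end single analysis: harmonization, instrument selection,
#' estimation (Wald ratio with a single instrument, all five estimators
#' with three or more), and the sensitivity suite.
#'
#' @param exposure,outcome Summary-statistics data frames.
#' @param ld Optional LD r-squared matrix for clumping.
#' @param criteria [instrument_criteria()] to apply.
#' @param n_boot,seed Bootstrap settings for median/mode estimators
#'   (`seed` required when 3+ instruments are available).
#' @param effects_model IVW effects model.
#' @param drop_palindromic Remove palindromic SNPs during harmonization.
#' @return List: `estimates` (per-method data frame), `sensitivity`
#'   (one-row report), `instruments` (pair table), `exclusions`,
#'   `stage_counts`.
#' @export
run_mr <- function(exposure, outcome, ld = NULL,
                   criteria = instrument_criteria(), n_boot = 1000,
                   seed = NULL, effects_model = "multiplicative_random",
                   drop_palindromic = TRUE) {
  h <- harmonize(exposure, outcome, drop_palindromic)
  sel <- select_instruments(h$pairs, ld, criteria)
  est <- mr_all(sel$instruments, n_boot = n_boot, seed = seed,
                effects_model = effects_model)
  sens <- sensitivity_report(sel$instruments)
  list(estimates = est, sensitivity = sens, instruments = sel$instruments,
       exclusions = rbind(h$exclusions, sel$exclusions),
       stage_counts = sel$stage_counts)
}

# IVW when several instruments survive, Wald ratio when exactly one.
.leg_estimate <- function(exposure, outcome, ld, criteria, effects_model) {
  h <- harmonize(exposure, outcome, drop_palindromic = TRUE)
  sel <- select_instruments(h$pairs, ld, criteria)
  pr <- sel$instruments
  est <- if (nrow(pr) == 1) mr_wald_ratio(pr) else mr_ivw(pr, effects_model)
  list(estimate = est, n_snp = nrow(pr), stage_counts = sel$stage_counts)
}

#' Two-step MR mediation analysis for one pathway
#'
#' Estimates the three legs of an exposure -> mediator -> outcome pathway
#' by two-sample MR (IVW, or Wald ratio when a single instrument
#' survives): beta1 from exposure->mediator, beta2 from mediator->outcome,
#' beta3 (the total effect) from exposure->outcome; then applies the
#' product-of-coefficients decomposition.
#'
#' @param exposure,mediator,outcome Summary-statistics data frames.
#' @param ld Optional LD r-squared matrix for clumping (shared SNP
#'   universe).
#' @param criteria Instrument criteria for the exposure-instrumented legs.
#' @param criteria_mediator Criteria for the mediator->outcome leg
#'   (defaults to `criteria`).
#' @param effects_model IVW effects model.
#' @return List: `mediation` ([two_step_mediation()] result), `legs`
#'   (per-leg `mr_estimate`s), `n_snp` per leg.
#' @export
run_mediation <- function(exposure, mediator, outcome, ld = NULL,
                          criteria = instrument_criteria(),
                          criteria_mediator = criteria,
                          effects_model = "multiplicative_random") {
  leg1 <- .leg_estimate(exposure, mediator, ld, criteria, effects_model)
  leg2 <- .leg_estimate(mediator, outcome, ld, criteria_mediator, effects_model)
  leg3 <- .leg_estimate(exposure, outcome, ld, criteria, effects_model)
  med <- two_step_mediation(leg1$estimate$beta, leg2$estimate$beta,
                            leg3$estimate$beta,
                            se1 = leg1$estimate$se, se2 = leg2$estimate$se)
  list(mediation = med,
       legs = list(exposure_mediator = leg1$estimate,
                   mediator_outcome = leg2$estimate,
                   exposure_outcome = leg3$estimate),
       n_snp = c(exposure_mediator = leg1$n_snp,
                 mediator_outcome = leg2$n_snp,
                 exposure_outcome = leg3$n_snp))
}

#' Mediation table across pathways
#'
#' Runs [run_mediation()] for each pathway, BH-adjusts the total-effect
#' p-values within the batch (the multiple-testing family is this set of
#' pathways), applies the dual significance rule to the total effect, and
#' separates pathways passing the sign-consistency rule (reported table)
#' from those failing it (kept in the `suppressed` log, numbers
#' unaltered). Pathways where any leg fails instrument selection are
#' skipped with a log entry.
#'
#' @param pathways Named list; each element a list with elements
#'   `exposure`, `mediator`, `outcome` (summary-statistics frames) and
#'   optional `label`.
#' @param ... Passed to [run_mediation()].
#' @param alpha_raw,alpha_adjusted Dual-rule thresholds.
#' @return List: `table` (reported rows: pathway, total/direct/mediation
#'   effects, proportion (%), p, p_adjusted, significant), `suppressed`
#'   (rows failing sign consistency), `skipped` (pathway, reason).
#' @export
run_mediation_pipeline <- function(pathways, ..., alpha_raw = 0.05,
                                   alpha_adjusted = 0.10) {
  labels <- names(pathways)
  if (is.null(labels)) labels <- paste0("pathway_", seq_along(pathways))
  rows <- list()
  skipped <- data.frame(pathway = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_along(pathways)) {
    pw <- pathways[[i]]
    res <- tryCatch(
      run_mediation(pw$exposure, pw$mediator, pw$outcome, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped, data.frame(pathway = labels[i],
                                           reason = conditionMessage(res)))
      next
    }
    m <- res$mediation
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = labels[i],
      total_effect = m$beta3, direct_effect = m$direct_effect,
      mediation_effect = m$mediation_effect,
      proportion = m$proportion,
      proportion_pct = if (is.na(m$proportion)) NA_character_ else
        format_proportion(m$proportion),
      se_mediation = m$se_mediation,
      p_total = res$legs$exposure_outcome$pvalue,
      consistent = m$consistent, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab) && nrow(tab)) {
    tab$p_total_adjusted <- bh_adjust(tab$p_total)
    tab$significant <- flag_significant(tab$p_total, tab$p_total_adjusted,
                                        alpha_raw, alpha_adjusted)
  }
  list(table = if (is.null(tab)) tab else tab[tab$consistent, , drop = FALSE],
       suppressed = if (is.null(tab)) tab else tab[!tab$consistent, , drop = FALSE],
       skipped = skipped)
}

#' Write an MR results table as TSV
#' @param x Data frame (e.g. from [mr_all()] or
#'   [run_mediation_pipeline()]).
#' @param path Output path.
#' @param header Optional comment lines (prefixed `#`) describing the run,
#'   e.g. the multiple-testing family.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, header = NULL) {
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
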