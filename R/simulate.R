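#' Configuration for the synthetic summary-statistics generator
#'
#' Describes a three-trait (exposure, mediator, outcome) generative model
#' with known causal structure. SNPs are partitioned into exposure
#' instruments (per-SNP exposure effects gamma ~ N(0, gamma_sd^2)) and
#' mediator-specific instruments (direct mediator effects
#' delta ~ N(0, delta_sd^2), no exposure effect) — the mediator needs its
#' own genetic component for the mediator->outcome leg of a two-step MR to
#' be estimable. True per-SNP effects are then
#' \deqn{mediator_j = b_1\gamma_j + \delta_j + \pi_j,\qquad
#'       outcome_j = b_{direct}\gamma_j + b_2\,mediator_j,}
#' with \eqn{\pi_j} a horizontal-pleiotropy term (nonzero for a configured
#' fraction of SNPs), so the implied total exposure->outcome effect is
#' `b_direct + b1*b2` and the implied proportion mediated is
#' `b1*b2 / (b_direct + b1*b2)`.
#'
#' Genotypes are treated as standardized, so the sampling standard error
#' of an observed effect at minor allele frequency `maf` and sample size
#' `n` is `1/sqrt(2*n*maf*(1-maf))`; observed betas are drawn normal
#' around their true values with that SD. Binary traits are emulated by
#' reading betas as log-odds. EAFs are shared across the three traits.
#'
#' @param n_snps Total number of SNPs (default 200).
#' @param seed Master seed (mandatory; per-trait noise streams are derived
#'   from it deterministically).
#' @param maf_range Interval for per-SNP minor allele frequencies
#'   (default c(0.05, 0.5)).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (default 1e5).
#' @param gamma_sd SD of true per-SNP exposure effects (default 0.05).
#' @param delta_sd SD of mediator-specific effects (default 0.05).
#' @param mediator_snp_fraction Fraction of SNPs that are
#'   mediator-specific instruments (default 0.5).
#' @param b1 True exposure->mediator effect (default 0.3).
#' @param b2 True mediator->outcome effect (default -0.2).
#' @param b_direct True direct exposure->outcome effect (default -0.5).
#' @param pleiotropy_fraction Fraction of SNPs with a pleiotropic mediator
#'   effect (default 0).
#' @param pleiotropy_sd SD of pleiotropic effects (default 0.05).
#' @param ld_block_size SNPs per LD block (default 1 = independent SNPs).
#' @param ld_within_block_r2 r-squared between SNPs of one block
#'   (default 0.8).
#' @param exact When `TRUE`, observed betas equal true betas (the
#'   infinite-sample limit); standard errors are still reported.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200, seed, maf_range = c(0.05, 0.5),
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 1e5,
                       gamma_sd = 0.05, delta_sd = 0.05,
                       mediator_snp_fraction = 0.5,
                       b1 = 0.3, b2 = -0.2, b_direct = -0.5,
                       pleiotropy_fraction = 0, pleiotropy_sd = 0.05,
                       ld_block_size = 1, ld_within_block_r2 = 0.8,
                       exact = FALSE) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed", call. = FALSE)
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exposure > 2, n_mediator > 2, n_outcome > 2,
            gamma_sd > 0, delta_sd > 0,
            mediator_snp_fraction >= 0, mediator_snp_fraction <= 1,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            pleiotropy_sd >= 0, ld_block_size >= 1,
            ld_within_block_r2 >= 0, ld_within_block_r2 <= 1)
  structure(list(n_snps = as.integer(n_snps), seed = as.integer(seed) %% 2147483600L,
                 maf_range = maf_range, n_exposure = n_exposure,
                 n_mediator = n_mediator, n_outcome = n_outcome,
                 gamma_sd = gamma_sd, delta_sd = delta_sd,
                 mediator_snp_fraction = mediator_snp_fraction,
                 b1 = b1, b2 = b2, b_direct = b_direct,
                 pleiotropy_fraction = pleiotropy_fraction,
                 pleiotropy_sd = pleiotropy_sd,
                 ld_block_size = as.integer(ld_block_size),
                 ld_within_block_r2 = ld_within_block_r2,
                 exact = isTRUE(exact)),
            class = "sim_config")
}

.sim_snp_ids <- function(n) sprintf("rs%06d", seq_len(n))

# Block layout: blocks of `ld_block_size` consecutive SNPs on chromosome 1,
# 10 kb apart within a block, 20 Mb between block starts (so the clumping
# window never spans two blocks).
.sim_positions <- function(config) {
  block <- (seq_len(config$n_snps) - 1L) %/% config$ld_block_size
  within <- (seq_len(config$n_snps) - 1L) %% config$ld_block_size
  list(chrom = rep("1", config$n_snps),
       pos = block * 2e7 + within * 1e4 + 1)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate aligned exposure, mediator and outcome summary statistics
#'
#' Draws one realization of the generative model described in
#' [sim_config()]: shared structural quantities (MAFs, true effects,
#' pleiotropy assignment) from the master seed, then an independent
#' sampling-noise stream per trait derived from it. Identical configs give
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return List with summary-statistics frames `exposure`, `mediator`,
#'   `outcome` (canonical columns, alleles A/G) and `truth`, a list
#'   holding the per-SNP true effects (`snps` data frame with `gamma`,
#'   `delta`, `pleio` and true per-trait betas), the structural
#'   coefficients, the implied total effect `beta3 = b_direct + b1*b2`,
#'   and the implied `proportion_mediated`.
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  ids <- .sim_snp_ids(n)
  loc <- .sim_positions(config)

  shared <- .with_seed(config$seed, {
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    n_med_snps <- round(n * config$mediator_snp_fraction)
    is_med <- seq_len(n) > (n - n_med_snps)
    gamma <- ifelse(is_med, 0, stats::rnorm(n, 0, config$gamma_sd))
    delta <- ifelse(is_med, stats::rnorm(n, 0, config$delta_sd), 0)
    pleio <- numeric(n)
    k <- floor(config$pleiotropy_fraction * n)
    if (k > 0) {
      which_p <- sample.int(n, k)
      pleio[which_p] <- stats::rnorm(k, 0, config$pleiotropy_sd)
    }
    list(maf = maf, gamma = gamma, delta = delta, pleio = pleio)
  })
  maf <- shared$maf
  exposure_true <- shared$gamma
  mediator_true <- config$b1 * shared$gamma + shared$delta + shared$pleio
  outcome_true <- config$b_direct * shared$gamma + config$b2 * mediator_true

  make_trait <- function(true_beta, n_samp, stream) {
    se <- 1 / sqrt(2 * n_samp * maf * (1 - maf))
    beta <- if (config$exact) true_beta else
      .with_seed(config$seed + stream, true_beta + stats::rnorm(n, 0, se))
    p <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    as_sumstats(data.frame(snp = ids, chrom = loc$chrom, pos = loc$pos,
                           effect_allele = "A", other_allele = "G",
                           eaf = maf, beta = beta, se = se, pvalue = p,
                           n = n_samp, stringsAsFactors = FALSE))
  }
  beta3 <- config$b_direct + config$b1 * config$b2
  list(exposure = make_trait(exposure_true, config$n_exposure, 1L),
       mediator = make_trait(mediator_true, config$n_mediator, 2L),
       outcome = make_trait(outcome_true, config$n_outcome, 3L),
       truth = list(
         snps = data.frame(snp = ids, gamma = shared$gamma,
                           delta = shared$delta, pleio = shared$pleio,
                           exposure_true = exposure_true,
                           mediator_true = mediator_true,
                           outcome_true = outcome_true,
                           stringsAsFactors = FALSE),
         b1 = config$b1, b2 = config$b2, b_direct = config$b_direct,
         beta3 = beta3,
         proportion_mediated = if (beta3 == 0) NA_real_ else
           config$b1 * config$b2 / beta3))
}

#' Simulate a block-diagonal LD (r-squared) matrix
#'
#' Within each block of `ld_block_size` consecutive SNPs, every pair has
#' `ld_within_block_r2`; between blocks, 0; diagonal 1. SNP ids match
#' [simulate_sumstats()].
#'
#' @param config A [sim_config()] object.
#' @return Symmetric r-squared matrix with SNP-id dimnames.
#' @export
simulate_ld <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  ids <- .sim_snp_ids(n)
  block <- (seq_len(n) - 1L) %/% config$ld_block_size
  m <- outer(block, block, "==") * config$ld_within_block_r2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a simulated dataset to disk
#'
#' Writes the three summary-statistic tables in the delimited format
#' [read_sumstats()] reads, plus the per-SNP truth as a sidecar TSV.
#'
#' @param sim Result of [simulate_sumstats()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$mediator, paths["mediator"])
  write_sumstats(sim$outcome, paths["outcome"])
  utils::write.table(sim$truth$snps, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
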