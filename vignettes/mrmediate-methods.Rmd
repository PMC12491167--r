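---
title: "Methods: two-sample MR, mediation, and SMR/HEIDI in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation, and SMR/HEIDI in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

This vignette records the statistical model behind each stage of the
pipeline, the defaults and why they were chosen, the numerical decisions
that matter for reproducibility, and what the synthetic-data generator
does and does not demonstrate about real data.

## The causal model and its assumptions

Two-sample MR treats each SNP $j$ as an instrument: with
$\hat\beta_{X,j}$ its estimated effect on the exposure and
$\hat\beta_{Y,j}$ on the outcome (from non-overlapping samples), the
per-SNP Wald ratio $\hat\beta_{Y,j}/\hat\beta_{X,j}$ estimates the causal
effect under the three instrumental-variable assumptions: association
with the exposure, independence from confounders, and no effect on the
outcome except through the exposure. Every estimator here is a different
way of pooling the ratios that fails gracefully under different
violations of the third assumption:

* **IVW** regresses $\hat\beta_Y$ on $\hat\beta_X$ through the origin
  with weights $1/se_Y^2$ — efficient, but biased by any directional
  pleiotropy.
* **MR-Egger** frees the intercept; the slope stays consistent under
  directional pleiotropy when instrument strength is independent of the
  direct effects, and the intercept itself is the pleiotropy test.
  Instruments are oriented so $\hat\beta_X \ge 0$ before fitting, which
  makes the intercept well defined and the fit invariant to allele
  re-orientation.
* **Weighted median** is consistent while at least half the instrument
  weight is valid.
* **Weighted/simple mode** estimate the ratio shared by the largest
  cluster of instruments (the "plurality valid" assumption); the simple
  variant drops the weights.

For binary traits all betas are log-odds; estimates are reported with
$OR = e^\beta$ and the 95% interval $e^{\beta \pm 1.96\,se}$.

### Effects model and p-values

The IVW default is multiplicative random effects: the fixed-effects
standard error is inflated by $\max(1, \sqrt{Q/(n-1)})$, so
heterogeneity widens intervals but the standard error never drops below
its fixed-effects value. The fixed-effects model is available by flag;
neither is asserted as uniquely correct, and single-instrument analyses
reduce exactly to the Wald ratio. p-values are two-sided normal for
Wald, IVW, median and mode estimators, and from $t_{n-2}$ for the Egger
slope and intercept (the regression estimates a residual dispersion).
The Wald-ratio standard error uses the first-order delta method
$se_Y/|\hat\beta_X|$ by default; the second-order form that also
propagates exposure-side noise is a flag, and the two agree closely
whenever $se_X/|\hat\beta_X|$ is small — which the F-statistic filter
enforces.

## Instrument selection

`instrument_criteria()` bundles the thresholds, applied in a fixed
order: exposure p-value ($<5\times10^{-6}$, the suggestive threshold
that keeps enough instruments for polygenic, modest-heritability
exposures like microbial abundances), minor allele frequency
($\ge 0.01$, computed as $\min(EAF, 1-EAF)$), greedy LD clumping
(drop SNPs with $r^2 \ge 0.01$ within 10,000 kb of a better-associated
index SNP; ties on p broken lexicographically by SNP id so runs are
deterministic), the outcome-association policy, and the weak-instrument
rule $F \le 10$. Each excluded SNP is logged once, at the first stage
that removed it, and retained + excluded always partitions the input.
The three pure per-SNP threshold filters commute; the order only
affects which label a doubly-failing SNP receives.

**The outcome-association filter is genuinely ambiguous** as a
published rule: excluding SNPs *associated* with the outcome
(p < 0.05) guards against instruments that act through confounders,
while the literal opposite reading (exclude p > 0.05) would keep only
outcome-associated SNPs. The package defaults to `exclude_below`
(drop outcome-associated SNPs) because that matches the stated purpose
of minimizing confounding, and offers `exclude_above` and `off`.
Note the filter is only coherent when the true causal effect is weak:
under a strong effect every valid instrument is outcome-associated and
`exclude_below` empties the set — which is why the recovery experiment
below runs with the filter off.

Harmonization aligns outcome effects to the exposure's effect allele
(swapped alleles negate the beta and complement the EAF), reconciles
strand flips by complementing alleles before comparison, removes
palindromic A/T and C/G SNPs by default (their strand cannot be
resolved from alleles alone; the remove-all default is conservative,
and no allele-frequency rescue is attempted), drops SNPs missing from
the outcome without proxy substitution, and excludes irreconcilable
allele sets rather than guessing. Duplicated SNP ids are an error, not
a silent dedup.

## Sensitivity diagnostics

Cochran's $Q=\sum_j w_j(\hat\beta_j-\hat\beta)^2$ with IVW weights
(df $n-1$ against the IVW estimate, $n-2$ against the Egger fit)
flags heterogeneity; leave-one-out recomputes the estimate $n$ times;
the Egger intercept tests directional pleiotropy; MR-Steiger compares
the summed variance explained in exposure versus outcome, with a
Fisher-z test on $\mathrm{atanh}\sqrt{R^2}$ at the two sample sizes.
Steiger ties resolve to `correct_direction = FALSE` with p = 1 — a tie
is never evidence of reverse causation.

**Power** uses a non-centrality normal approximation for binary
outcomes,
$power = \Phi(\nu - z_{1-\alpha/2}) + \Phi(-\nu - z_{1-\alpha/2})$ with
$\nu = \sqrt{n\,R^2\,\phi(1-\phi)}\,|\log OR|$ for case fraction
$\phi$. This formula is a declared convention of this package (tested
against a Monte-Carlo IVW oracle), chosen because it reduces to
$\alpha$ at $OR=1$ and needs only quantities the pipeline already has.
The conventional screen drops exposures with power < 0.5 against a
plausible alternative.

## Two-step mediation

With $\beta_1$ (exposure→mediator), $\beta_2$ (mediator→outcome) and
$\beta_3$ (total, exposure→outcome), the decomposition is the product
of coefficients: mediated $=\beta_1\beta_2$, direct
$=\beta_3-\beta_1\beta_2$, proportion $=\beta_1\beta_2/\beta_3$.
Additivity holds exactly by construction. Three conventions matter:

* $\beta_1$ lives on the log-odds scale — an upstream estimate reported
  as an OR enters as $\log OR$.
* A mediated effect opposing the total in sign is arithmetically valid
  but not interpretable as partial mediation; such pathways carry
  `consistent = FALSE` and are moved to a suppressed log, with the
  numbers untouched.
* Proportions format as percentages with three decimals; a zero total
  effect makes the proportion undefined (`NA`), never an exception.

The optional standard error of the mediated effect is the first-order
delta method $\sqrt{\beta_2^2 se_1^2 + \beta_1^2 se_2^2}$; no interval
is offered for the proportion.

Multiple testing uses Benjamini–Hochberg within an analysis batch (the
set of pathways, or methods, submitted together) — the family
definition is written into the output header because no single choice
is canonical. The dual significance rule flags raw p < 0.05 *and*
adjusted p < 0.10.

## SMR and HEIDI

The SMR statistic
$T_{SMR} = z_{GWAS}^2 z_{eQTL}^2/(z_{GWAS}^2+z_{eQTL}^2)$ is bounded by
the smaller of the two squared z-scores, so a marginal eQTL cannot
manufacture significance. HEIDI compares each eligible cis SNP's
implied $b_{SMR}$ to the top SNP's: the statistic is the sum of squared
standardized differences, whose null law is a weighted sum of 1-df
chi-squares with weights the eigenvalues of the correlation matrix of
the differences. The covariance propagates both eQTL and GWAS sampling
error through the signed LD correlation $r$ by the first-order delta
method (the two samples are independent, so there are no cross terms).

Numerical choices:

* The tail probability of the weighted chi-square sum is evaluated by
  Imhof's characteristic-function inversion with adaptive quadrature
  (a finite oscillatory panel plus the transformed tail; a
  single-component case is evaluated exactly; a Satterthwaite
  two-moment match is the fallback if quadrature fails). Accuracy is
  ~1e-5 in the regimes tested.
* Eligibility defaults — eQTL p < 1.57e-3, LD $r^2$ with the top SNP in
  [0.05, 0.9], between 3 and 20 SNPs — follow the conventions of the
  established SMR tooling; none is claimed to be the published study's
  setting, and all are config-exposed. Fewer than 3 eligible SNPs make
  the HEIDI p undefined, which *fails* the decision rule with a recorded
  reason.
* The delta-method covariance assumes the eQTL effects are estimated
  with small relative error. Calibration checks in the test suite show
  nominal size (≈5% at the 0.05 level, uniform p) when eQTL z-scores
  are large, and inflation (~8–9%) when eQTL noise rivals GWAS noise;
  the eligibility p-threshold keeps analyses in the calibrated regime.
* HEIDI needs *signed* LD correlations; the clumping interface consumes
  $r^2$. For simulated block LD (non-negative correlation by
  construction) `sqrt()` converts one to the other.

The decision rule — p_SMR < 0.10 and p_HEIDI > 0.05 — passes genes with
evidence of an expression-outcome association not better explained by
linkage.

## The synthetic-data generator

`simulate_sumstats()` draws a three-trait summary-statistics study with
known causal structure. SNPs are partitioned into exposure instruments
($\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$) and mediator-specific
instruments ($\delta_j \sim N(0, \texttt{delta\_sd}^2)$, no exposure
effect); true effects are
$$\text{mediator}_j = b_1\gamma_j + \delta_j + \pi_j,\qquad
  \text{outcome}_j = b_{direct}\gamma_j + b_2\,\text{mediator}_j,$$
with $\pi_j$ a pleiotropy term on a configurable fraction of SNPs.
The mediator *must* have instruments of its own: if every
mediator-associated SNP acted through the exposure, the
mediator→outcome Wald ratio would identify $b_2 + b_{direct}/b_1$
rather than $b_2$, and no two-step design could recover the mediated
proportion. Observed betas are true betas plus
$N(0, 1/\sqrt{2n\,maf(1-maf)}^2)$ noise (standardized-genotype
convention), with EAFs shared across traits, one master seed, and
deterministic per-trait noise streams. Binary traits are emulated by
reading betas as log-odds; the sampling model is unchanged. LD is
block-diagonal: `ld_within_block_r2` inside blocks laid out 20 Mb
apart so the default clumping window never spans blocks.

Defaults are one fixed set of study conditions, chosen once:
200 SNPs, $n=10^5$ per trait, `gamma_sd = delta_sd = 0.05` (so a
realistic minority of SNPs clear the $5\times10^{-6}$ threshold at
$n=10^5$), half the SNPs mediator-specific, $b_1=0.3$, $b_2=-0.2$,
$b_{direct}=-0.5$ (implied total $-0.56$, proportion mediated
$\approx 0.107$), no pleiotropy.

**What the generator does not emulate**: realistic LD from reference
panels, allele-frequency spectra, sample overlap between the two
samples, binary-trait likelihoods (betas are Gaussian around truth),
winner's-curse-free discovery (instruments are selected in the same
data that estimates them, as in most real two-sample MR), or
population stratification. Passing recovery tests therefore shows the
pipeline arithmetic and its statistical calibration are right under
the stated model — not that any real exposure→mediator→outcome claim
is correct.

**A known, quantified bias**: exposure instruments also associate with
the mediator (through $b_1$), so the mediator→outcome leg's instrument
set is contaminated by SNPs whose ratio is $b_2 + b_{direct}/b_1$.
Under the default conditions this inflates the estimated mediated
proportion by roughly +0.03–0.04 absolute; the same phenomenon affects
real two-step MR whenever exposure and mediator share genetics. The
replicated recovery experiment (median over 200 replicates within
±0.05 of truth) passes with this bias included, and the vignette
records it rather than hiding it.

## Problem sizes and runtime choices

The replicated experiments run at sizes chosen to give tight
Monte-Carlo error while staying comfortable on a laptop: 200 replicates
for the recovery of the mediated proportion (median MC error ≈ 0.004),
1000 replicates for the Egger-intercept type-I error (binomial 95%
half-width ≈ 0.0135 around 0.05), 500–1000 replicates for HEIDI
calibration, and 10,000–100,000 draws for the delta-method Monte-Carlo
oracles. Bootstrap standard errors default to 1000 resamples with a
mandatory seed — there is no silent nondeterminism anywhere in the
package; every stochastic routine either takes a seed or restores the
RNG state it found.

## Known limitations

* No genome-build liftover, no proxy-SNP lookup, no reference-panel LD
  computation — LD is an input.
* No MR-PRESSO/multivariable-MR/CAUSE estimators, no I² statistic, no
  colocalization beyond HEIDI, and no confidence interval for the
  mediated proportion.
* The power formula is an approximation suited to screening, not a
  substitute for study-specific power simulation.
* Mediation arithmetic is exact, but its causal reading still rests on
  the untestable IV assumptions of each leg.
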