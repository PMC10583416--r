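---
title: "Two-step mediation Mendelian randomization for drug targets"
author: "medimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation Mendelian randomization for drug targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medimr)
```

## The problem

Drug-target Mendelian randomization (MR) uses genetic variants in or near
the gene encoding a drug's target as instruments for pharmacological
modulation of that target.  When the variants are scaled by their effect
on a downstream biomarker (for SGLT2 inhibition, glycated hemoglobin),
the resulting estimate reads as the effect of a 1 SD biomarker lowering
via the target — a genetic proxy for treatment.  Two-step (mediation) MR
then asks *how much* of a protective total effect on a binary outcome
such as atrial fibrillation flows through an intermediate: a circulating
metabolite.  medimr implements the full workflow on two-sample GWAS
summary statistics:

1. instrument selection (eQTL region filter, biomarker significance,
   approximate-Bayes-factor colocalization gate, greedy LD clumping,
   per-variant F statistics);
2. allele harmonization across traits;
3. the univariable estimator battery — IVW, MR-Egger, weighted median,
   simple and weighted mode — with Cochran's Q;
4. outlier diagnostics run *before* the main fit (MR-PRESSO, radial MR);
5. multivariable MR (MV-IVW, MVMR-Egger);
6. product-of-coefficients mediation with a delta-method CI;
7. a Bonferroni-corrected screening cascade over a mediator panel;
8. a seeded synthetic-data generator with known ground truth.

## Models and assumptions

All estimators act on a `HarmonizedSet`: per-variant effects
$(\hat\beta_{Xj}, \sigma_{Xj})$ on the exposure(s) and
$(\hat\beta_{Yj}, \sigma_{Yj})$ on the outcome, expressed per copy of a
common effect allele.  The instrumental-variable assumptions are the
usual ones (relevance, independence, exclusion restriction); each method
relaxes exclusion differently.

**IVW.** The main analysis: weighted least squares of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with weights
$w_j = 1/\sigma_{Yj}^2$, i.e.
$\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum_j w_j
\hat\beta_{Xj}^2$.  The default is the multiplicative random-effects
variant: the fixed-effect SE is inflated by
$\max\{1, \sqrt{Q/(J-1)}\}$, so homogeneous data fall back to the
fixed-effect SE and heterogeneous data are penalized.  Inference is
normal-based.

**MR-Egger.** The same regression with an intercept, after orienting all
variants so $\hat\beta_{Xj} \ge 0$.  A nonzero intercept indicates
directional pleiotropy; the slope is consistent under the InSIDE
assumption.  SEs carry a $\max\{1,\text{dispersion}\}$ factor with
dispersion$^2 = Q_{\text{res}}/(J-2)$ and both slope and intercept use
t inference with $J-2$ df — Egger regression is systematically less
precise, and t-based intervals acknowledge the small-$J$ setting.

**Weighted median.** The 0.5 crossing of the cumulative-midpoint weights
over the sorted per-variant ratios, with weights
$(\hat\beta_{Xj}/\sigma_{Yj})^2$.  Consistent when valid instruments
carry at least half the total weight.  The SE comes from a parametric
bootstrap (effects resampled from their estimation normals; the seed is
mandatory, making results reproducible).

**Mode-based estimates.** The argmax of a normal-kernel density of the
ratios over a 1,000-point grid, unweighted (simple) or inverse-variance
weighted.  Bandwidth $b = \phi \cdot 0.9\min(\mathrm{sd},
\mathrm{mad})\,J^{-1/5}$ with $\phi = 1$; `mad` uses the sd-consistent
1.4826 scaling.  Consistent when the largest cluster of instruments is
valid.  If all ratios coincide the bandwidth degenerates to zero and the
estimate is the common ratio.

**MR-PRESSO.** The observed statistic is the leave-one-out residual sum
of squares; its null distribution is simulated by redrawing both
exposure and outcome effects from their estimation normals (the
leave-one-out fits are recomputed inside every replicate).  Monte-Carlo
p-values use the add-one rule $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$,
which can never return zero; per-variant p-values are
Bonferroni-adjusted by $J$.  The distortion test compares the
corrected-vs-full change in $\hat\theta$ against removal of equally many
random variants.

**Radial MR.** With first-order weights $W_j =
\hat\beta_{Xj}^2/\sigma_{Yj}^2$ the radial regression reproduces IVW
exactly (this identity is asserted in the tests at $10^{-10}$), but
decomposes Q into per-variant contributions referred to
$\chi^2_1$; outliers are removed and the fit iterated.  The pipeline
removes the *union* of MR-PRESSO and radial outliers before every MR
fit, treating both as pre-filters rather than gates.

**Colocalization.** Per-variant Wakefield log approximate Bayes factors
$\tfrac12[\log(1-r) + r z^2]$, $r = W/(V+W)$, combined under the
single-causal-variant model into posterior probabilities of H0–H4.  All
hypothesis sums are carried in log space with log-sum-exp so that
regions with $z \sim 40$ cannot overflow.  Default priors are the
field-standard $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, with prior
effect SD 0.2 for quantitative and 0.15 for binary traits; the source
analysis states only the decision rule (PP.H4 > 0.7), so these defaults
are this package's documented choice.

**MVMR and mediation.** MV-IVW regresses the outcome effects on the full
exposure-effect matrix (no intercept, weights $1/\sigma_{Yj}^2$); the
mediator's coefficient adjusted for the exposure is $\beta_2$.  With
$\beta_1$ the exposure-to-mediator IVW estimate and $\theta_{tot}$ the
total effect, the indirect effect is $\beta_1\beta_2$ and the mediated
proportion $\beta_1\beta_2/\theta_{tot}$, with
$\mathrm{se}_{\text{ind}} = \sqrt{\beta_1^2\mathrm{se}_2^2 +
\beta_2^2\mathrm{se}_1^2}$ (first-order delta; no covariance term — the
two estimates come from non-overlapping regressions in the two-sample
design; the second-order $\mathrm{se}_1^2\mathrm{se}_2^2$ term is
available via `second_order = TRUE`).

A deliberate design choice: the proportion SE treats the total effect as
**fixed**, $\mathrm{se}_{\text{prop}} =
\mathrm{se}_{\text{ind}}/|\theta_{tot}|$.  With the published worked
example (0.42, OR 0.88, OR 0.51) this reproduces the published interval
to within rounding, whereas the full ratio delta method (switchable with
`total_fixed = FALSE`) yields a markedly wider interval.  Both are
implemented; the default is the one that matches the reporting
convention of the analyses this package emulates.

Reports also print `exp(indirect)` as an "indirect-effect OR" alongside
the adjusted mediator-on-outcome OR, because published mediation tables
are ambiguous about which of the two is meant; the two are labeled
distinctly and neither is guessed to be the other.

## Instrument selection conventions

* Drug-target route: eQTL variants inside the gene region, biomarker
  association $p < 10^{-4}$, optional colocalization gate, permissive
  clumping $r^2 < 0.8$ within 250 kb.  The permissive threshold means
  retained instruments may be correlated; downstream estimators
  nonetheless use the independent-instrument working model, mirroring
  the practice this package reimplements.  This is a documented
  limitation, not an oversight.
* Biomarker/metabolite route: genome-wide $p < 5\times10^{-8}$,
  clumping $r^2 < 0.01$ within 10,000 kb.
* Clumping is greedy by p-value with lexicographic variant-id
  tie-breaking (determinism); a variant is removed only when it is both
  in LD with a kept variant **and** within the window.
* Per-variant $F = (\hat\beta/\mathrm{se})^2$, the squared Wald z; F < 10
  flags a weak instrument.
* `invert_sign` negates the exposure betas so the axis reads "per 1 SD
  biomarker lowering" — inhibition — without touching allele labels
  (the association itself is unchanged; only the exposure direction is).

**Harmonization.** Traits are aligned to the first exposure's effect
allele; swapped alleles flip the beta and mirror the eaf;
strand-complement matches are resolved before dropping.  Palindromic
(A/T, C/G) variants cannot be strand-resolved from alleles: policy
`drop_all` removes them, `infer_by_eaf` keeps them when every trait's
eaf lies outside [0.42, 0.58] and orients by frequency agreement.  The
window and the rule "missing eaf on a palindrome means drop" are this
package's documented defaults; the source analyses leave harmonization
implicit.

## The synthetic-data generator

`simulateMRStudy()` draws summary statistics directly on the summary
scale: no individual-level genotypes, which keeps a full study under a
millisecond and matches the two-sample assumptions exactly.  Defaults
*are* the study conditions used throughout the tests: 10 exposure
instruments, MAF uniform on [0.1, 0.4], sample sizes 300,000 per trait,
$\beta_1 = 0.42$, $\beta_2 = \ln 0.88$, direct effect chosen so
$\theta_{tot} = \ln 0.51$ (true mediated proportion 7.97%), instrument
explained variance 3% per trait, no pleiotropy.  Observed effects are
truth plus $N(0, \mathrm{se}^2)$ noise with the analytic
$\mathrm{se} = 1/\sqrt{2p(1-p)n}$; binary-outcome effects are generated
on the log-odds scale directly rather than via a liability threshold
(the entire pipeline operates on log-odds; a documented simplification).

Two structural choices deserve emphasis:

* **Each mediator gets its own instruments.**  If mediator effects
  existed only at the exposure's SNPs, the exposure and mediator columns
  of the MVMR design would be exactly collinear and the adjusted
  $\beta_2$ unidentifiable.  Each panel mediator therefore receives
  `n_med_snps` independent SNPs (exposure effect zero there), which is
  also how real metabolite GWAS provide instruments.
* **Non-overlapping samples by construction.**  Noise draws are
  independent across traits; a shared-noise correlation
  (`sample_overlap_rho`) is provided for sensitivity analyses of sample
  overlap but defaults to zero.

Planted outliers displace the outcome effect of chosen instruments by
`outlier_scale` (default 10) outcome SEs and are recorded in the truth.
`simulateColocRegion()` builds AR(1)-correlated regions
($z \sim N(R\lambda, R)$) for the five colocalization scenarios.

What the generator does **not** emulate: real LD between instruments
(the study LD matrix is identity; LD structure appears only in the
clumping/colocalization test beds), winner's curse in instrument
selection, liability-scale binary traits, and correlated pleiotropy
violating InSIDE.  Passing tests therefore demonstrate correctness of
the estimators and pipeline under the stated model, not robustness to
every failure mode of real GWAS data.

## Numerical choices

* Weighted regressions use explicit normal equations on small, well-
  conditioned designs; tests verify equality with `lm` solutions at
  $10^{-10}$ on random instances.
* Dispersion floors: IVW $\max\{1,\sqrt{Q/(J-1)}\}$; Egger df $J-2$;
  MV-IVW df $J-k$; MVMR-Egger df $J-k-1$.
* 95% CIs are normal-based except the Egger family (t-based), matching
  the distributions used for p-values.
* Bootstrap and simulation sizes default to 1,000; every stochastic
  routine takes a mandatory seed and is bit-reproducible.
* Monte-Carlo p-values use the add-one rule, bounded below by
  $1/(n_{sim}+1)$.
* Degenerate inputs are handled explicitly: one-variant IVW degrades to
  the Wald ratio with a warning; zero-bandwidth mode returns the common
  ratio; zero exposure effects are excluded from radial MR with a
  warning, and are an error in the Wald ratio.
* p-values written by the generator are clamped at $10^{-300}$ to stay
  inside (0, 1].

## Problem sizes used by the test-suite simulations

Chosen as the smallest sizes at which the checked properties are stable:
1,000 replicates for IVW calibration, 200 seeds for mediated-proportion
recovery (median within 1.5 percentage points of truth), 50 seeds for
the full 31-mediator cascade, 20 seeds for outlier flagging and for the
colocalization H4 detection rate.  The whole suite runs in about a
minute on one core.

## A worked run

```{r example}
study <- simulateMRStudy(simulationConfig(seed = 42, n_mediator_panel = 5))
cfg <- pipelineConfig(
  exposure = study$exposure_stats,
  mediators = study$mediator_stats,
  outcome = study$outcome_stats,
  ld = study$ld,
  invert_sign = FALSE,   # generator effects are already on the causal axis
  methods = c("ivw", "egger", "weighted_median"),
  n_boot = 200, n_sim = 500, seed = 42)
report <- runTwoStepPipeline(cfg)
report$table1[, c("method", "or", "or_low", "or_high", "pval")]
report$mediation[, c("mediator", "proportion_pct", "ci_low_pct",
                     "ci_high_pct", "pval")]
study$truth$proportion_true * 100
```

## Known limitations

* Instrument correlation after permissive clumping is ignored by all
  estimators (no generalized-least-squares IVW).
* Single-causal-variant colocalization only; no SuSiE-style multiple
  signals, no conditioning.
* No MR-RAPS, debiased IVW, second-order radial weights, or
  multi-exposure MR-PRESSO.
* The mediation decomposition handles one mediator at a time; no joint
  multiple-mediator decomposition.
* Ratio SEs are first-order (exposure uncertainty enters only through
  the bootstrap-based estimators).
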