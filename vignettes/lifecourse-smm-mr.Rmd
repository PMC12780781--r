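---
title: "Lifecourse Mendelian randomization with structural mean models"
author: "lifecourseMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifecourse Mendelian randomization with structural mean models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecourseMR)
```

## The problem

Genetic variants often influence a modifiable trait with different strength
at different ages.  Adiposity is the canonical example: one set of SNPs
predicts body size around age 10 better than in adulthood, another set the
reverse.  A standard Mendelian randomization (MR) analysis that pools all
variants estimates a *lifetime* effect and cannot say whether an early-life
exposure harms (or protects) directly, or only because it tracks into the
later exposure.  `lifecourseMR` implements the two estimator families that
address this, together with a synthetic cohort generator rich enough to
exercise every stage without access-restricted biobank data:

* **g-estimation of additive structural mean models (SMMs)** on
  individual-level data, univariable (period effects) and multivariable
  (controlled period effects), instrumented by polygenic risk scores (PRSs);
* **inverse-variance-weighted (IVW) MR** on summary statistics, univariable
  and multivariable (IVW-MVMR), for comparison.

All contrasts are on the **risk-difference scale**: the outcome model is
linear in probability, so a coefficient is the change in outcome risk per
unit (or per tier) of exposure.

## Estimands and regimes

For exposure measures $X_1$ (early period) and $X_2$ (late period) and a
binary outcome $Y$, the additive SMM parameter $\psi$ solves the moment
condition

$$\sum_i (z_i - \bar z)\,(y_i - \psi x_i) = 0,$$

which forces the instrument to be uncorrelated with the residual of the
counterfactual outcome.  The solution is the Wald ratio
$\hat\psi = \widehat{\mathrm{cov}}(z,y)/\widehat{\mathrm{cov}}(z,x)$.  The
multivariable version stacks one moment per instrument,

$$\mathbb{E}\big[(Z - \mathbb{E}Z)(Y - X^\top\psi)\big] = 0,$$

and solves the $M \times K$ system through the instrument–exposure
cross-covariance (just-identified) or through a two-stage projection of the
exposures on all instruments (over-identified; the two-stage least-squares
weighting).

The same arithmetic identifies different causal contrasts depending only on
*when* the instruments are assumed to act on the exposure.  The package
makes that explicit: every estimate carries an `EstimandRegime` — `point`,
`period`, `lifetime`, or `controlled-period` — whose assumption text comes
from a fixed internal registry (`estimandRegistry()`).  The regime is
metadata, never a different formula.  No separate point-effect estimator
exists: instruments credibly acting at a single time point are rarely
defensible, and the univariable arithmetic would be unchanged.

A consequence the package surfaces directly: when the early exposure tracks
into the late one with coefficient $\theta$ and both have direct effects
$\psi_1, \psi_2$, a univariable analysis with early-only instruments
converges to the **total early-period effect** $\psi_1 + \theta\psi_2$, not
to $\psi_1$.  Only the multivariable (controlled) analysis separates
$\psi_1$ from $\psi_2$.  `mediationScenario()` demonstrates this
attenuation pattern by Monte Carlo, and `runAnalysis()` reports the correct
target for every row because the generating truth is known.

## The synthetic cohort

`generateCohort()` draws, deterministically from a `SimulationTruth`:

* genotypes: $J$ independent biallelic SNPs, $G_{ij} \sim
  \mathrm{Binomial}(2, f_j)$ (Hardy–Weinberg, no linkage disequilibrium);
* a standard-normal latent confounder $U$;
* exposures
  $X_1 = (G - 2f)^\top\alpha_1 + c_1 U + \varepsilon_1$ and
  $X_2 = \theta X_1 + (G - 2f)^\top\alpha_2 + c_2 U + \varepsilon_2$;
* outcome risk $p = b_0 + \psi_1 X_1 + \psi_2 X_2 + c_y U$, clamped to
  $[\varepsilon, 1-\varepsilon]$, then $Y \sim \mathrm{Bernoulli}(p)$;
* 3-tier recodings of both exposures (`categorizeThreeTier()`): the lowest
  $\lfloor n p_1 \rfloor$ ranked values are "thinner", the next block
  "average", the rest "plumper", with stable original-order tie-breaking.
  Both exposures use the same proportions so estimates are comparable
  across periods, mirroring how a recall-style categorical measure is
  matched by recoding a continuous one.

Genetic contributions enter as deviations from the population genotype mean
$2f_j$.  This is deliberate: without it, the realized sum
$\sum_j \alpha_j 2f_j$ shifts the mean risk by up to $\pm 0.1$ depending on
the signs drawn for a particular design, pushing the linear-probability
model against its boundary.  With centering, `baselineRisk` is the actual
mean risk.  No estimator is affected — all are covariance-based.

**Clamping is the validity diagnostic.** The linear-probability model
identifies risk differences only while predicted risks stay inside the unit
interval.  The fraction of clamped risks is recorded in the cohort metadata
(`clampFraction()`), reported by the pipeline, and a fraction above 1%
raises a warning (an error with `strict = TRUE`).  Under the default design
the worst-seed fraction is about 0.2%.

### The standard design

`defaultSimulationTruth()` fixes the study conditions: 20,000 individuals;
100 SNPs of which 40 act only on the early exposure, 40 only on the late
one, and 20 on both; allele frequencies uniform on $(0.1, 0.5)$; per-allele
effects of 0.05–0.08 with random signs; tracking $\theta = 0.3$; confounder
loadings 0.4 and 0.25 on the exposures and 0.05 on risk; exposure noise SDs
1 and 0.5; baseline risk 0.3; controlled period effects
$(\psi_1, \psi_2) = (-0.02, 0.10)$.  These values give strong instruments
(oracle-score first-stage F near 1000 at $n = 20{,}000$), a confounded
observational association, a realistic attrition of instrument counts
across stringency tiers, and predicted risks comfortably inside the unit
interval.  The negative-early/positive-late effect pair reproduces the
qualitative pattern reported for adiposity and cardiometabolic disease:
harmful late-period effect, protective controlled early-period effect,
positive total early-period effect ($\psi_1 + \theta\psi_2 = 0.01$).

### What the generator does not emulate

Linkage disequilibrium (so clumping is a no-op by construction),
relatedness and population stratification (so ordinary least squares
replaces a mixed model in the association scans), selection into the
cohort, measurement error in the recall variable beyond the 3-tier
coarsening, exposure–period interactions, and time-varying confounding
(one shared confounder loads on everything).  Passing tests therefore
validate the estimators and the selection logic under the stated model,
not robustness to these real-data complications.

## Association scans and instrument tiers

`assocScan()` regresses a trait on each SNP's allele count (plus optional
covariates, via Frisch–Waugh residualization, which reproduces the multiple
regression fit exactly).  Binary traits are scanned on the linear
probability scale so SNP–outcome effects share units with the SMM
estimands.  P-values use the two-sided normal approximation on
$\hat\beta/\mathrm{se}$ — the GWAS summary-statistics convention — with the
residual variance keeping its $n - C - 2$ degrees of freedom.  SNPs without
genotype variance are flagged `monomorphic` and never become instrument
candidates.

`selectInstruments()` implements four stringency tiers for a target
exposure.  Candidates must reach genome-wide significance
($p \le 5\times10^{-8}$) for the target; the tiers then exclude SNPs
associated with the *other* period's exposure at $p \le 5\times10^{-8}$
(low-medium), at a Bonferroni-corrected $p \le 0.05/m$ (medium-high), or at
$p \le 0.05$ (high).  Retention requires the other-period p-value to be
*strictly greater* than the threshold, matching the exclusion phrasing.
The Bonferroni denominator $m$ pools the counts of early-specific and
late-specific variants surviving the strictest exclusion in both
directions (`bonferroniThreshold()`); the pooled denominator is applied to
both exposures' medium-high tiers.  With tracking $\theta > 0$, every
early-period SNP has a genuine late-exposure association of size
$\theta\alpha_1$, so stringent tiers legitimately thin out — and at large
discovery samples may empty — the early instrument set.  This is the
central selection phenomenon the tiers exist to expose, not an artifact.

Polygenic scores are weighted allele-count sums with discovery betas as
weights (`computePRS()`).  Unweighted scores can be had by passing unit
weights, but weighted scores are the default since the discovery scan is
available in every pipeline run.

## Inference

**Sandwich (default).** With moment contributions
$g_i = (Z_i - \bar Z)(y_i - X_i^\top\hat\psi)$, the variance is
$A^{-1} B A^{-\top}/n$ with $A = n^{-1}\sum (Z_i - \bar Z) X_i^\top$ and
$B$ the second moment of the $g_i$.  One numerical subtlety: the additive
SMM's baseline is estimated alongside $\psi$, so $B$ must use
*mean-centered* residuals.  Leaving the residual mean in inflates $B$
whenever $\mathbb{E}[Y - \psi^\top X] \neq 0$ (which is generic for binary
outcomes) — in a check at $n = 400$ the uncentered form overstated the
empirical sampling SD by about a third, and nominal 95% coverage would be
lost.  Confidence intervals use the normal quantile 1.959964.

**Bootstrap.** Nonparametric case resampling (`bootstrapSE()`), SE from the
replicate SD and percentile intervals, deterministic given a seed; more
than 10% failed replicates is an error.

**IVW.** `ivwUnivariable()` is the zero-intercept weighted regression of
SNP–outcome on SNP–exposure betas with weights $1/\mathrm{se}_Y^2$;
`ivwMvmr()` is its $K$-exposure weighted-least-squares generalization, to
which it reduces exactly at $K = 1$.  Standard errors carry a
multiplicative random-effects scale $\max(1, \sqrt{Q/\mathrm{df}})$ — the
common summary-MR default, floored at 1 so homogeneous data keep the
fixed-effect SE.  `harmonize()` aligns effect alleles first, flipping betas
for swapped allele pairs and dropping incompatible ones with a report.

## Numerical choices and degenerate inputs

* Instrument relevance: the univariable denominator must exceed
  $10^{-12}\, n\, \mathrm{sd}(z)\,\mathrm{sd}(x)$; a constant instrument is
  an immediate error.
* Multivariable separability: the instrument–exposure cross-covariance must
  have condition number below $10^{10}$ (singular-value ratio), else the
  instruments "do not separate exposures".
* Risk clamp $\varepsilon = 10^{-6}$; clamp-fraction ceiling 1%.
* Tier ties: stable original-order ranking, so degenerate (all-equal)
  exposures still split exactly by the floor arithmetic.
* Non-binary outcomes are accepted by the SMM estimators but flagged, since
  the estimates are then mean differences rather than risk differences.
* Covariates, when supplied to an estimator, residualize instrument,
  exposure and outcome before estimation — the same adjustment the
  association scans apply, kept optional because the analysis stage of the
  source design leaves it unstated.

## The pipeline and sample designs

`runAnalysis()` chains simulate → scan → select → score → estimate across
all requested tiers and frameworks, emitting one row per
exposure × tier × framework with estimate, SE, CI, regime label,
first-stage diagnostics and the generating-truth target
($\psi_1 + \theta\psi_2$ for univariable early, $\psi_2$ for univariable
late, $(\psi_1, \psi_2)$ for controlled).  Under `sampleDesign =
"split-sample"` the discovery scans use a random half of the cohort and
estimation the other half; `"one-sample"` uses the full cohort for both,
mirroring the fully overlapping design of a single-biobank analysis.  With
weak instruments the one-sample design is biased toward the confounded
observational association — the package's test suite demonstrates the
bias direction by simulation.  Exposures enter estimation on their
continuous scale by default; `exposureCoding = "tier"` switches to the
ordinal 1–3 coding of the recall-style recodings (per-tier risk
differences; generating-truth targets are then undefined and reported as
`NA`).  Empty tier selections are reported and skipped; the run continues.

`mediationScenario()` repeats cohort generation under a
$\psi_1 \le 0,\ \psi_2 > 0,\ \theta \ge 0$ truth with *oracle*
period-specific instruments (true effect weights on SNPs acting on exactly
one period), isolating the structural attenuation phenomenon from
instrument-selection noise.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` size their simulations as a
desk-scale study: closed-form and oracle equivalences on 1000 / 200 random
small instances; controlled-effect recovery over 200 replicate cohorts of
20,000; the mediation pattern over 150–200 replicates of 10,000; sandwich
coverage over 500–1000 replicates of 5,000; scan calibration on 1000 null
SNPs at 5,000.  These sizes give Monte-Carlo standard errors a few times
smaller than the effects being checked while keeping a full run in minutes
on one core.

## Known limitations

Only additive (risk-difference) SMMs are implemented — no multiplicative,
logistic or time-to-event variants, no doubly-robust augmentation, and no
weak-instrument-robust confidence sets.  IVW has no MR-Egger intercept,
median/mode estimators, or correlated-SNP extension.  The generator's
independence assumptions (no LD, no relatedness, no selection) are exactly
the conditions under which ordinary least squares is the right scan and
clumping is unnecessary; none of the machinery here validates those
assumptions on real data.
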