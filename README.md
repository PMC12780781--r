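# lifecourseMR

Lifecourse Mendelian randomization (MR) with g-estimation of additive
structural mean models (SMMs).

Genetic effects on a modifiable trait can differ across the lifecourse:
some variants predict early-life adiposity, others adult adiposity, many
both.  A standard MR analysis pools them and estimates a *lifetime* effect,
which cannot tell whether an early exposure acts on disease directly or
only by tracking into the later exposure.  `lifecourseMR` implements, and
lets you stress-test on fully synthetic cohorts:

* **univariable SMM g-estimation** — the period-effect estimator
  `smmUnivariable()`, solving
  `sum_i (z_i − z̄)(y_i − ψ x_i) = 0`, i.e. the Wald ratio
  `ψ̂ = cov(z, y) / cov(z, x)` with a polygenic risk score (PRS) as
  instrument `z`;
* **multivariable SMM g-estimation** — `smmMultivariable()`, solving the
  stacked moments `E[(Z − EZ)(Y − X'ψ)] = 0` for controlled period effects
  `(ψ₁, ψ₂)` of the early and late exposures jointly;
* **IVW and IVW-MVMR** on summary statistics (`ivwUnivariable()`,
  `ivwMvmr()`) for comparison, with multiplicative random-effects SEs;
* **tiered instrument selection** (`selectInstruments()`): four stringency
  levels that progressively exclude SNPs associated with the other
  period's exposure (at 5e-8, at a pooled-count Bonferroni threshold, at
  0.05), plus `bonferroniThreshold()` and `computePRS()`;
* a **synthetic cohort generator** (`generateCohort()`) with
  period-specific SNP effects, exposure tracking, a shared unmeasured
  confounder, linear-probability (risk-difference) binary outcomes, and
  recall-style 3-tier exposure recoding;
* an **end-to-end pipeline** (`runAnalysis()`) and a Monte-Carlo
  **mediation scenario** (`mediationScenario()`).

All causal contrasts are risk differences per unit of exposure.  Every
estimate carries an explicit *estimand regime* (point / period / lifetime /
controlled-period): the same numbers identify different causal contrasts
depending only on when the instruments are assumed to act on the exposure.

## Worked example

Simulate the standard study design — 20,000 individuals, 100 SNPs (40
early-specific, 40 late-specific, 20 shared), tracking θ = 0.3, true
controlled period effects (ψ₁, ψ₂) = (−0.02, 0.10) — then scan, select
instruments, build scores and estimate:

```r
library(lifecourseMR)

truth <- defaultSimulationTruth(seed = 7)
cfg   <- analysisConfig(truth, tiers = c("low", "low-medium"),
                        frameworks = c("smm-uni", "smm-multi", "ivw-mvmr"))
run   <- runAnalysis(cfg, quiet = TRUE)
run
```

```
lifecourseRun: 12 estimates ( one-sample design, n = 20000 )
 exposure estimator       tier   estimand_regime      psi      se   ci_low
    early   smm-uni        low            period  0.01650 0.01330 -0.00965
     late   smm-uni        low            period  0.10400 0.00992  0.08490
    early smm-multi        low controlled-period -0.02550 0.01390 -0.05270
     late smm-multi        low controlled-period  0.10900 0.01050  0.08820
    early  ivw-mvmr        low controlled-period -0.02340 0.01290 -0.04880
     late  ivw-mvmr        low controlled-period  0.11000 0.01040  0.08920
    early   smm-uni low-medium            period -0.00255 0.01560 -0.03320
     late   smm-uni low-medium            period  0.10800 0.01090  0.08670
    early smm-multi low-medium controlled-period -0.02570 0.01560 -0.05630
     late smm-multi low-medium controlled-period  0.10900 0.01110  0.08770
    early  ivw-mvmr low-medium controlled-period -0.02290 0.01430 -0.05090
     late  ivw-mvmr low-medium controlled-period  0.11100 0.01110  0.08890
 ci_high     n first_stage_F true_value
 0.04270 20000           965       0.01
 0.12400 20000          4110       0.10
 0.00178 20000          1050      -0.02
 0.12900 20000          2850       0.10
 0.00193    68            NA      -0.02
 0.13000    68            NA       0.10
 0.02810 20000           700       0.01
 0.13000 20000          3270       0.10
 0.00499 20000           972      -0.02
 0.13100 20000          2470       0.10
 0.00499    62            NA      -0.02
 0.13200    62            NA       0.10
```

Reading the table: the univariable early-period estimate targets the
*total* early effect ψ₁ + θψ₂ = 0.01 — early-life adiposity looks harmful
(or null) because it tracks into the late exposure — while the controlled
(multivariable) estimates separate the direct effects, recovering the
protective early effect −0.02 and the harmful late effect 0.10 within
their confidence intervals.  IVW-MVMR on scan-derived summary statistics
(`n` there is the SNP count) agrees closely with the individual-level SMM,
as expected in this simple linear model.  `run$report` carries the
clamped-risk fraction (here 0.0018, i.e. the linear-probability model is
essentially unclamped), SNP counts per tier (23 early / 51 late at low
stringency), timings and the seed.

A thin command-line wrapper over these functions, with `simulate`, `scan`,
`select`, `score`, `estimate`, `run` and `scenario` subcommands, is in
`inst/cli/lifecourse-mr.R`.

## Vignette

`vignettes/lifecourse-smm-mr.Rmd` documents the generating model and its
assumptions, the estimand regimes, the instrument-selection tiers, the
sandwich/bootstrap inference (including why the moment residuals are
mean-centered), the numerical tolerances, and what the synthetic design
does and does not emulate about real cohort data.
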