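Package: lifecourseMR
Title: Lifecourse Mendelian Randomization with Structural Mean Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: G-estimation of additive structural mean models for lifecourse
    Mendelian randomization with tiered polygenic-score instruments, alongside
    inverse-variance-weighted univariable and multivariable estimators for
    comparison. Includes a synthetic one-sample cohort simulator with
    period-specific genetic effects, exposure tracking, shared confounding and
    linear-probability binary outcomes; per-SNP association scans; instrument
    selection under graded stringency thresholds; polygenic risk scoring; and
    an end-to-end pipeline that contrasts period, controlled-period and
    lifetime causal estimands on the risk-difference scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'assocScan.R'
    'cohort.R'
    'estimands.R'
    'io.R'
    'ivw.R'
    'smm.R'
    'prs.R'
    'pipeline.R'
    'reexports.R'
    'simulationTruth.R'
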