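#' @import methods
#' @importFrom stats rbinom rnorm runif cor var sd qnorm pnorm quantile
#'   complete.cases lm
#' @importFrom utils head read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowData "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

.TIER_LEVELS <- c("low", "low-medium", "medium-high", "high")
.TIER_LABELS <- c("thinner", "average", "plumper")
.PERIODS <- c("early", "late")

# ---------------------------------------------------------------------------
# SimulationTruth

#' SimulationTruth: the full data-generating model of a synthetic cohort
#'
#' Holds every parameter of the two-period lifecourse generating model:
#' independent biallelic SNPs in Hardy-Weinberg proportions; per-allele
#' effects \code{alpha1} on the early exposure and \code{alpha2} on the late
#' exposure (period-specific SNPs have one of the two zero, shared SNPs
#' neither); tracking of the early exposure into the late one
#' (\code{theta}); a standard-normal latent confounder with loadings on both
#' exposures and the outcome; and a linear-probability (risk-difference)
#' binary outcome model with controlled period effects \code{psi1},
#' \code{psi2}.
#'
#' @slot nIndividuals number of individuals to simulate.
#' @slot snpIds,effectAllele,otherAllele per-SNP identifiers and allele codes.
#' @slot maf effect-allele frequencies, in (0,1).
#' @slot alpha1,alpha2 per-allele effects on the early / late exposure.
#' @slot theta tracking coefficient of the early into the late exposure.
#' @slot confLoadX1,confLoadX2,confLoadY loadings of the latent confounder.
#' @slot sigma1,sigma2 exposure noise standard deviations (positive).
#' @slot baselineRisk outcome risk at zero exposure and confounder.
#' @slot psi1,psi2 true controlled period effects (risk difference per unit).
#' @slot tierProportions proportions for the 3-tier recall-style recoding.
#' @slot seed RNG seed; the cohort is a deterministic function of the truth.
#'
#' @seealso [simulationTruth()], [defaultSimulationTruth()], [generateCohort()]
#' @export
setClass("SimulationTruth", slots = c(
  nIndividuals   = "integer",
  snpIds         = "character",
  effectAllele   = "character",
  otherAllele    = "character",
  maf            = "numeric",
  alpha1         = "numeric",
  alpha2         = "numeric",
  theta          = "numeric",
  confLoadX1     = "numeric",
  confLoadX2     = "numeric",
  confLoadY      = "numeric",
  sigma1         = "numeric",
  sigma2         = "numeric",
  baselineRisk   = "numeric",
  psi1           = "numeric",
  psi2           = "numeric",
  tierProportions = "numeric",
  seed           = "integer"
))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  J <- length(object@maf)
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (any(object@maf <= 0) || any(object@maf >= 1))
    msg <- c(msg, "maf entries must lie strictly in (0,1)")
  for (s in c("snpIds", "effectAllele", "otherAllele", "alpha1", "alpha2"))
    if (length(slot(object, s)) != J)
      msg <- c(msg, sprintf("%s must have length %d (one per SNP)", s, J))
  for (s in c("theta", "confLoadX1", "confLoadX2", "confLoadY", "sigma1",
              "sigma2", "baselineRisk", "psi1", "psi2"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a finite scalar", s))
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    msg <- c(msg, "sigma1 and sigma2 must be positive")
  if (object@baselineRisk <= 0 || object@baselineRisk >= 1)
    msg <- c(msg, "baselineRisk must lie strictly in (0,1)")
  tp <- object@tierProportions
  if (length(tp) != 3L || any(tp < 0) || abs(sum(tp) - 1) > 1e-12)
    msg <- c(msg, "tierProportions must be a 3-vector summing to 1 (tol 1e-12)")
  if (anyDuplicated(object@snpIds)) msg <- c(msg, "snpIds must be unique")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# LifecourseCohort

#' LifecourseCohort: genotypes plus two-period phenotypes
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"genotypes"} assay
#' (SNPs as rows, individuals as columns, entries counting copies of the
#' effect allele) and per-individual phenotypes in \code{colData}: the
#' continuous exposures \code{x1} (early) and \code{x2} (late), their 3-tier
#' recall-style recodings \code{x1Tier}/\code{x2Tier}
#' (thinner < average < plumper), the binary outcome \code{y}, optionally the
#' latent confounder \code{u} and any covariate columns.  Simulated cohorts
#' carry their \linkS4class{SimulationTruth} and the clamped-risk fraction in
#' \code{metadata}; [observedCohort()] strips everything an analyst of real
#' data could not see.
#'
#' @seealso [generateCohort()], [lifecourseCohort()], [filterCompleteCases()]
#' @export
setClass("LifecourseCohort", contains = "SummarizedExperiment")

setValidity("LifecourseCohort", function(object) {
  msg <- character()
  if (!"genotypes" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotypes' is required")
  g <- assay(object, "genotypes")
  gv <- g[!is.na(g)]
  if (length(gv) && !all(gv == 0L | gv == 1L | gv == 2L))
    msg <- c(msg, "genotype entries must be in {0,1,2}")
  cd <- colData(object)
  need <- c("x1", "x2", "x1Tier", "x2Tier", "y")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  yv <- cd$y[!is.na(cd$y)]
  if (length(yv) && !all(yv == 0 | yv == 1))
    msg <- c(msg, "y entries must be in {0,1}")
  for (tc in c("x1Tier", "x2Tier")) {
    f <- cd[[tc]]
    if (!is.factor(f) || !identical(levels(f), .TIER_LABELS))
      msg <- c(msg, sprintf("%s must be a factor with levels %s", tc,
                            paste(.TIER_LABELS, collapse = " < ")))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# InstrumentSet

#' InstrumentSet: SNPs selected as instruments under one stringency tier
#'
#' @slot snpIds SNP identifiers.
#' @slot weights per-allele weights (discovery-scan betas for the target
#'   exposure, oriented to \code{effectAllele}).
#' @slot effectAllele allele whose count each weight multiplies.
#' @slot tier one of \code{"low"}, \code{"low-medium"}, \code{"medium-high"},
#'   \code{"high"} — increasingly strict exclusion of SNPs associated with the
#'   other period's exposure.
#' @slot targetPeriod \code{"early"} or \code{"late"}.
#' @seealso [selectInstruments()], [computePRS()]
#' @export
setClass("InstrumentSet", slots = c(
  snpIds       = "character",
  weights      = "numeric",
  effectAllele = "character",
  tier         = "character",
  targetPeriod = "character"
))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  n <- length(object@snpIds)
  if (length(object@weights) != n || length(object@effectAllele) != n)
    msg <- c(msg, "snpIds, weights and effectAllele must have equal length")
  if (!(length(object@tier) == 1L && object@tier %in% .TIER_LEVELS))
    msg <- c(msg, sprintf("tier must be one of %s",
                          paste(.TIER_LEVELS, collapse = ", ")))
  if (!(length(object@targetPeriod) == 1L &&
        object@targetPeriod %in% .PERIODS))
    msg <- c(msg, "targetPeriod must be 'early' or 'late'")
  if (anyDuplicated(object@snpIds)) msg <- c(msg, "snpIds must be unique")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EstimandRegime

#' EstimandRegime: which causal contrast an estimate is claimed to identify
#'
#' The same g-estimation arithmetic identifies a point, period or lifetime
#' effect depending only on what is assumed about when the instruments act on
#' the exposure; the multivariable framework identifies controlled period
#' effects.  The regime is therefore metadata attached to an estimate, never
#' a different formula.  Labels and assumption texts come from a fixed
#' internal registry; see [estimandRegime()].
#'
#' @slot label one of \code{"point"}, \code{"period"}, \code{"lifetime"},
#'   \code{"controlled-period"}.
#' @slot assumptionText the instrument-timing assumption under which the
#'   numeric estimate carries this interpretation.
#' @export
setClass("EstimandRegime", slots = c(
  label          = "character",
  assumptionText = "character"
))

.estimandRegistry <- list(
  "point" = paste(
    "The instruments affect the exposure only at the single time point",
    "considered, with no direct effect on the exposure at any other time;",
    "the estimate is the risk difference for a one-unit increase in the",
    "exposure at that time point."),
  "period" = paste(
    "The instruments exert a constant effect on the exposure throughout the",
    "target period and no direct effect on the exposure outside it; the",
    "estimate is the risk difference for a constant one-unit increase in the",
    "exposure sustained over that period."),
  "lifetime" = paste(
    "The instrument-exposure associations are uniform and constant from",
    "conception to the time the outcome is measured; the estimate is the",
    "risk difference for a one-unit increase in the exposure sustained over",
    "the entire lifecourse."),
  "controlled-period" = paste(
    "The instruments have distinct effects on the exposure in each modelled",
    "period; each estimate is the risk difference for a one-unit increase in",
    "the exposure of one period with the exposures at the other modelled",
    "periods held fixed."))

setValidity("EstimandRegime", function(object) {
  if (length(object@label) != 1L ||
      !object@label %in% names(.estimandRegistry))
    return(sprintf("label must be one of %s",
                   paste(names(.estimandRegistry), collapse = ", ")))
  if (!identical(object@assumptionText, .estimandRegistry[[object@label]]))
    return("assumptionText does not match the registry entry for this label")
  TRUE
})

# ---------------------------------------------------------------------------
# SmmEstimate

#' SmmEstimate: a g-estimated structural-mean-model causal contrast
#'
#' @slot psi causal estimates, risk difference per unit exposure (length K).
#' @slot se standard errors per \code{seMethod}.
#' @slot ciLow,ciHigh 95\% confidence limits.
#' @slot exposures exposure labels (length K).
#' @slot method \code{"smm-univariable"} or \code{"smm-multivariable"}.
#' @slot seMethod \code{"sandwich"} or \code{"bootstrap"}.
#' @slot regime the claimed \linkS4class{EstimandRegime}.
#' @slot nUsed number of individuals used.
#' @slot firstStageF instrument-strength diagnostics (marginal F for the
#'   univariable model, conditional F per exposure for the multivariable one).
#' @seealso [smmUnivariable()], [smmMultivariable()]
#' @export
setClass("SmmEstimate", slots = c(
  psi         = "numeric",
  se          = "numeric",
  ciLow       = "numeric",
  ciHigh      = "numeric",
  exposures   = "character",
  method      = "character",
  seMethod    = "character",
  regime      = "EstimandRegime",
  nUsed       = "integer",
  firstStageF = "numeric"
))

setValidity("SmmEstimate", function(object) {
  msg <- character()
  K <- length(object@psi)
  if (length(object@se) != K || length(object@ciLow) != K ||
      length(object@ciHigh) != K || length(object@exposures) != K)
    msg <- c(msg, "psi, se, ciLow, ciHigh, exposures must share length")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "se must be >= 0")
  if (any(object@ciLow > object@psi + 1e-12, na.rm = TRUE) ||
      any(object@ciHigh < object@psi - 1e-12, na.rm = TRUE))
    msg <- c(msg, "need ciLow <= psi <= ciHigh elementwise")
  if (!object@method %in% c("smm-univariable", "smm-multivariable"))
    msg <- c(msg, "method must be smm-univariable or smm-multivariable")
  if (!object@seMethod %in% c("sandwich", "bootstrap"))
    msg <- c(msg, "seMethod must be sandwich or bootstrap")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# IvwEstimate

#' IvwEstimate: inverse-variance-weighted summary-statistics MR estimate
#'
#' @slot beta causal estimates, one per exposure (length K).
#' @slot se standard errors after multiplicative random-effects scaling.
#' @slot ciLow,ciHigh 95\% confidence limits.
#' @slot exposures exposure labels.
#' @slot heterogeneityQ Cochran's Q of the weighted regression residuals.
#' @slot df residual degrees of freedom (J - K).
#' @slot reScale the multiplicative random-effects scale actually applied,
#'   \code{max(1, sqrt(Q/df))}.
#' @slot method \code{"ivw-univariable"} or \code{"ivw-mvmr"}.
#' @slot nSnps number of SNPs used.
#' @seealso [ivwUnivariable()], [ivwMvmr()]
#' @export
setClass("IvwEstimate", slots = c(
  beta           = "numeric",
  se             = "numeric",
  ciLow          = "numeric",
  ciHigh         = "numeric",
  exposures      = "character",
  heterogeneityQ = "numeric",
  df             = "integer",
  reScale        = "numeric",
  method         = "character",
  nSnps          = "integer"
))

setValidity("IvwEstimate", function(object) {
  msg <- character()
  K <- length(object@beta)
  if (length(object@se) != K || length(object@ciLow) != K ||
      length(object@ciHigh) != K || length(object@exposures) != K)
    msg <- c(msg, "beta, se, ciLow, ciHigh, exposures must share length")
  if (object@heterogeneityQ < 0) msg <- c(msg, "heterogeneityQ must be >= 0")
  if (object@reScale < 1) msg <- c(msg, "reScale must be >= 1")
  if (!object@method %in% c("ivw-univariable", "ivw-mvmr"))
    msg <- c(msg, "method must be ivw-univariable or ivw-mvmr")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# AnalysisConfig

#' AnalysisConfig: one end-to-end pipeline run
#'
#' @slot truth the \linkS4class{SimulationTruth} defining the cohort.
#' @slot tiers stringency tiers to run (subset of low, low-medium,
#'   medium-high, high).
#' @slot frameworks subset of \code{"smm-uni"}, \code{"smm-multi"},
#'   \code{"ivw-uni"}, \code{"ivw-mvmr"}.
#' @slot sampleDesign \code{"one-sample"} (discovery scan and estimation on
#'   the full cohort, mirroring fully overlapping samples) or
#'   \code{"split-sample"} (discovery on one half, estimation on the other).
#' @slot gwThreshold genome-wide significance threshold for target-trait
#'   association (default 5e-8).
#' @slot exposureCoding \code{"continuous"} (default) enters the measured
#'   exposures into estimation; \code{"tier"} enters the ordinal 1-3 coding
#'   of the thinner/average/plumper recodings, mirroring recall-style
#'   categorical measures (estimates are then risk differences per tier).
#' @slot nBoot bootstrap replicates when bootstrap SEs are requested.
#' @slot seed seed for the split assignment and any bootstrap.
#' @seealso [runAnalysis()], [analysisConfig()]
#' @export
setClass("AnalysisConfig", slots = c(
  truth        = "SimulationTruth",
  tiers        = "character",
  frameworks   = "character",
  sampleDesign = "character",
  gwThreshold  = "numeric",
  exposureCoding = "character",
  nBoot        = "integer",
  seed         = "integer"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!length(object@tiers) || !all(object@tiers %in% .TIER_LEVELS))
    msg <- c(msg, "tiers must be a nonempty subset of the four tiers")
  fw <- c("smm-uni", "smm-multi", "ivw-uni", "ivw-mvmr")
  if (!length(object@frameworks) || !all(object@frameworks %in% fw))
    msg <- c(msg, sprintf("frameworks must be a nonempty subset of {%s}",
                          paste(fw, collapse = ", ")))
  if (!(length(object@sampleDesign) == 1L &&
        object@sampleDesign %in% c("one-sample", "split-sample")))
    msg <- c(msg, "sampleDesign must be 'one-sample' or 'split-sample'")
  if (object@sampleDesign == "split-sample" &&
      object@truth@nIndividuals %% 2L != 0L)
    msg <- c(msg, "split-sample design requires an even number of individuals")
  if (object@gwThreshold <= 0 || object@gwThreshold >= 1)
    msg <- c(msg, "gwThreshold must be in (0,1)")
  if (!(length(object@exposureCoding) == 1L &&
        object@exposureCoding %in% c("continuous", "tier")))
    msg <- c(msg, "exposureCoding must be 'continuous' or 'tier'")
  if (length(msg)) msg else TRUE
})
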