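#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SimulationTruth
#'
#' Bundles every parameter of the two-period generating model.  See
#' \linkS4class{SimulationTruth} for the meaning of each argument and
#' [defaultSimulationTruth()] for the standard study design.
#'
#' @param nIndividuals cohort size.
#' @param maf effect-allele frequencies (length J, strictly in (0,1)).
#' @param alpha1,alpha2 per-allele effects on the early / late exposure
#'   (length J).
#' @param theta tracking coefficient of the early into the late exposure.
#' @param confLoadX1,confLoadX2,confLoadY loadings of the standard-normal
#'   latent confounder on the two exposures and on outcome risk.
#' @param sigma1,sigma2 exposure noise standard deviations.
#' @param baselineRisk outcome risk at zero exposures and confounder.
#' @param psi1,psi2 true controlled period effects (risk difference per unit
#'   exposure).
#' @param tierProportions proportions of the thinner/average/plumper recoding.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   truth object.
#' @param snpIds,effectAllele,otherAllele optional SNP ids and allele codes;
#'   defaults are rs-style ids with A as the counted allele and G as the
#'   other.
#' @return a validated \linkS4class{SimulationTruth}.
#' @examples
#' tr <- simulationTruth(nIndividuals = 100, maf = c(0.2, 0.4),
#'                       alpha1 = c(0.1, 0), alpha2 = c(0, 0.1),
#'                       theta = 0.3, psi1 = -0.02, psi2 = 0.1, seed = 1)
#' trueTotalEarlyEffect(tr)
#' @export
simulationTruth <- function(nIndividuals, maf, alpha1, alpha2,
                            theta = 0, confLoadX1 = 0, confLoadX2 = 0,
                            confLoadY = 0, sigma1 = 1, sigma2 = 1,
                            baselineRisk = 0.3, psi1 = 0, psi2 = 0,
                            tierProportions = c(1, 1, 1) / 3, seed = 1L,
                            snpIds = NULL, effectAllele = NULL,
                            otherAllele = NULL) {
  J <- length(maf)
  if (is.null(snpIds)) snpIds <- sprintf("rs%05d", seq_len(J))
  if (is.null(effectAllele)) effectAllele <- rep("A", J)
  if (is.null(otherAllele)) otherAllele <- rep("G", J)
  new("SimulationTruth",
      nIndividuals = as.integer(nIndividuals),
      snpIds = as.character(snpIds),
      effectAllele = as.character(effectAllele),
      otherAllele = as.character(otherAllele),
      maf = as.numeric(maf),
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      theta = as.numeric(theta),
      confLoadX1 = as.numeric(confLoadX1),
      confLoadX2 = as.numeric(confLoadX2),
      confLoadY = as.numeric(confLoadY),
      sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2),
      baselineRisk = as.numeric(baselineRisk),
      psi1 = as.numeric(psi1), psi2 = as.numeric(psi2),
      tierProportions = as.numeric(tierProportions),
      seed = as.integer(seed))
}

#' The standard synthetic study design
#'
#' A two-period cohort with period-specific and shared SNPs: \code{nEarly}
#' SNPs act only on the early exposure, \code{nLate} only on the late one,
#' and \code{nShared} on both.  Allele frequencies are drawn uniformly on
#' \code{mafRange} and per-allele effects uniformly on
#' \code{effectSizeRange}, both deterministically from \code{seed}.  The
#' defaults — 20,000 individuals, 100 SNPs (40/40/20), per-allele effects
#' of 0.05-0.08, tracking 0.3, confounder loadings 0.4/0.25 on the exposures
#' and 0.05 on risk, baseline risk 0.3, controlled period effects
#' (psi1, psi2) = (-0.02, 0.10) — give strong instruments, a confounded
#' observational association, and a clamped-risk fraction well below the 1%
#' validity ceiling of the linear-probability outcome model.
#'
#' @param seed integer seed controlling both the design draw and the cohort.
#' @param nIndividuals cohort size.
#' @param nEarly,nLate,nShared numbers of early-specific, late-specific and
#'   shared SNPs.
#' @param effectSizeRange range of per-allele effect magnitudes.
#' @param mafRange range of effect-allele frequencies.
#' @param theta,confLoadX1,confLoadX2,confLoadY,sigma1,sigma2,baselineRisk,psi1,psi2,tierProportions
#'   as in [simulationTruth()].
#' @return a \linkS4class{SimulationTruth}.
#' @examples
#' tr <- defaultSimulationTruth(seed = 7, nIndividuals = 1000)
#' @export
defaultSimulationTruth <- function(seed = 1L, nIndividuals = 20000L,
                                   nEarly = 40L, nLate = 40L, nShared = 20L,
                                   effectSizeRange = c(0.05, 0.08),
                                   mafRange = c(0.1, 0.5),
                                   theta = 0.3, confLoadX1 = 0.4,
                                   confLoadX2 = 0.25, confLoadY = 0.05,
                                   sigma1 = 1, sigma2 = 0.5,
                                   baselineRisk = 0.3,
                                   psi1 = -0.02, psi2 = 0.10,
                                   tierProportions = c(1, 1, 1) / 3) {
  J <- nEarly + nLate + nShared
  design <- withSeed(seed, {
    maf <- runif(J, mafRange[1], mafRange[2])
    a1 <- runif(J, effectSizeRange[1], effectSizeRange[2]) *
      sample(c(-1, 1), J, replace = TRUE)
    a2 <- runif(J, effectSizeRange[1], effectSizeRange[2]) *
      sample(c(-1, 1), J, replace = TRUE)
    list(maf = maf, a1 = a1, a2 = a2)
  })
  early <- seq_len(nEarly)
  late <- nEarly + seq_len(nLate)
  alpha1 <- design$a1
  alpha2 <- design$a2
  alpha1[late] <- 0      # late-specific SNPs do not touch the early exposure
  alpha2[early] <- 0     # early-specific SNPs act on x2 only via tracking
  simulationTruth(nIndividuals = nIndividuals, maf = design$maf,
                  alpha1 = alpha1, alpha2 = alpha2, theta = theta,
                  confLoadX1 = confLoadX1, confLoadX2 = confLoadX2,
                  confLoadY = confLoadY, sigma1 = sigma1, sigma2 = sigma2,
                  baselineRisk = baselineRisk, psi1 = psi1, psi2 = psi2,
                  tierProportions = tierProportions, seed = seed)
}

#' @rdname trueTotalEarlyEffect
#' @export
setMethod("trueTotalEarlyEffect", "SimulationTruth", function(object)
  object@psi1 + object@theta * object@psi2)

#' Indices of period-specific SNPs in a SimulationTruth
#'
#' SNPs acting on exactly one period's exposure (directly; tracking-induced
#' associations do not count).  Used for oracle instrument sets in
#' simulation studies.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param period \code{"early"} or \code{"late"}.
#' @return integer vector of SNP indices.
#' @export
periodSpecificSnps <- function(truth, period = c("early", "late")) {
  period <- match.arg(period)
  if (period == "early") which(truth@alpha1 != 0 & truth@alpha2 == 0)
  else which(truth@alpha2 != 0 & truth@alpha1 == 0)
}

setMethod("show", "SimulationTruth", function(object) {
  J <- length(object@maf)
  cat("SimulationTruth:", object@nIndividuals, "individuals,", J, "SNPs\n")
  cat(sprintf("  period-specific SNPs: %d early, %d late; %d shared\n",
              length(periodSpecificSnps(object, "early")),
              length(periodSpecificSnps(object, "late")),
              sum(object@alpha1 != 0 & object@alpha2 != 0)))
  cat(sprintf("  theta = %.3g; psi = (%.3g, %.3g); total early effect %.3g\n",
              object@theta, object@psi1, object@psi2,
              trueTotalEarlyEffect(object)))
  cat(sprintf("  confounder loadings (x1, x2, y) = (%.3g, %.3g, %.3g)\n",
              object@confLoadX1, object@confLoadX2, object@confLoadY))
  cat(sprintf("  baseline risk %.3g; seed %d\n",
              object@baselineRisk, object@seed))
})

#' Read and write SimulationTruth sidecar files
#'
#' The truth is serialized as YAML with one entry per slot, so a simulated
#' cohort written to disk can be regenerated or audited.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path file path.
#' @return \code{readTruth} returns a \linkS4class{SimulationTruth};
#'   \code{writeTruth} returns \code{path} invisibly.
#' @export
writeTruth <- function(truth, path) {
  sl <- slotNames(truth)
  x <- lapply(sl, function(s) slot(truth, s))
  names(x) <- sl
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(simulationTruth, x)
}
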