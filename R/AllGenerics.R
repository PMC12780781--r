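#' @include AllClasses.R
NULL

#' Total early-period effect implied by the generating model
#'
#' For a simulated cohort the effect of a one-unit increase in the early
#' exposure, allowed to track into the late exposure, is
#' \code{psi1 + theta * psi2} on the risk-difference scale.  This is the
#' quantity a univariable analysis with early-period instruments targets.
#'
#' @param object a \linkS4class{SimulationTruth}.
#' @return numeric scalar risk difference.
#' @export
setGeneric("trueTotalEarlyEffect", function(object)
  standardGeneric("trueTotalEarlyEffect"))

#' @rdname lifecourseAccessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname lifecourseAccessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' @rdname lifecourseAccessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname lifecourseAccessors
#' @export
setGeneric("regime", function(object) standardGeneric("regime"))

#' @rdname lifecourseAccessors
#' @export
setGeneric("firstStageF", function(object) standardGeneric("firstStageF"))

#' @rdname cohortAccessors
#' @export
setGeneric("genotypeMatrix", function(object) standardGeneric("genotypeMatrix"))

#' @rdname cohortAccessors
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @rdname cohortAccessors
#' @export
setGeneric("clampFraction", function(object) standardGeneric("clampFraction"))

#' @rdname cohortAccessors
#' @export
setGeneric("observedCohort", function(object) standardGeneric("observedCohort"))

#' Per-individual polygenic risk scores
#'
#' Weighted sum of effect-allele counts over the SNPs of an
#' \linkS4class{InstrumentSet}: \code{score_i = sum_j w_j G_ij}.
#'
#' @param genotypes a \linkS4class{LifecourseCohort} or an individuals-by-SNPs
#'   integer matrix with SNP ids as column names.
#' @param instruments an \linkS4class{InstrumentSet}.
#' @return numeric vector of length n (individuals).
#' @export
setGeneric("computePRS", function(genotypes, instruments)
  standardGeneric("computePRS"))
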