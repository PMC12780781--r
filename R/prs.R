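#' @include AllClasses.R AllGenerics.R
NULL

#' Bonferroni-corrected exclusion threshold from period-specific SNP counts
#'
#' The number of early-period-specific and late-period-specific variants
#' (those surviving the strictest cross-period exclusion) are pooled and
#' 0.05 is divided by their total.
#'
#' @param countEarlySpecific,countLateSpecific nonnegative variant counts.
#' @return the corrected p-value threshold \code{0.05 / (sum of counts)}.
#' @examples
#' bonferroniThreshold(55, 218)   # 0.05 / 273
#' @export
bonferroniThreshold <- function(countEarlySpecific, countLateSpecific) {
  if (countEarlySpecific < 0 || countLateSpecific < 0)
    stop("counts must be nonnegative", call. = FALSE)
  total <- countEarlySpecific + countLateSpecific
  if (total == 0)
    stop("at least one period-specific variant is required", call. = FALSE)
  0.05 / total
}

#' Select instruments under a stringency tier
#'
#' Candidates are SNPs associated with the target exposure at
#' \code{p <= gwThreshold} (genome-wide significance).  Increasing tiers then
#' exclude SNPs associated with the other period's exposure:
#' \describe{
#'   \item{low}{no exclusion — kept regardless of the other-period
#'     association.}
#'   \item{low-medium}{exclude SNPs with \code{p_other <= gwThreshold}.}
#'   \item{medium-high}{exclude SNPs with \code{p_other <= bonferroni}; when
#'     \code{bonferroni} is NULL it is computed by [bonferroniThreshold()]
#'     from the pooled counts of high-tier period-specific SNPs in the two
#'     scans supplied.}
#'   \item{high}{exclude SNPs with \code{p_other <= 0.05}.}
#' }
#' Exclusion uses non-strict \code{<=}, so retention requires the
#' other-period p-value to be strictly greater than the threshold.  Weights
#' are the discovery betas for the target exposure, oriented to the effect
#' allele.  Monomorphic records are never candidates.
#'
#' @param statsTarget SummaryStats for the target exposure.
#' @param statsOther SummaryStats for the other period's exposure, indexed by
#'   the same SNP ids.
#' @param tier one of \code{"low"}, \code{"low-medium"}, \code{"medium-high"},
#'   \code{"high"}.
#' @param gwThreshold genome-wide significance threshold (default 5e-8).
#' @param bonferroni optional corrected threshold for the medium-high tier.
#' @param targetPeriod \code{"early"} or \code{"late"} (metadata).
#' @return an \linkS4class{InstrumentSet}.
#' @export
selectInstruments <- function(statsTarget, statsOther,
                              tier = c("low", "low-medium", "medium-high",
                                       "high"),
                              gwThreshold = 5e-8, bonferroni = NULL,
                              targetPeriod = c("early", "late")) {
  tier <- match.arg(tier)
  targetPeriod <- match.arg(targetPeriod)
  .assertScalarProb(gwThreshold, "gwThreshold")
  st <- statsTarget
  if (!is.null(st$monomorphic)) st <- st[!st$monomorphic, , drop = FALSE]
  cand <- st[!is.na(st$pval) & st$pval <= gwThreshold, , drop = FALSE]
  if (tier != "low") {
    pOther <- statsOther$pval[match(cand$snp, statsOther$snp)]
    if (anyNA(pOther))
      stop("no other-period p-value for candidate SNP(s): ",
           paste(head(cand$snp[is.na(pOther)], 5L), collapse = ", "),
           call. = FALSE)
    thr <- switch(tier,
      "low-medium" = gwThreshold,
      "medium-high" = {
        if (is.null(bonferroni)) {
          nTS <- .countHighTier(statsTarget, statsOther, gwThreshold)
          nOS <- .countHighTier(statsOther, statsTarget, gwThreshold)
          bonferroni <- bonferroniThreshold(nTS, nOS)
        }
        .assertScalarProb(bonferroni, "bonferroni")
        bonferroni
      },
      "high" = 0.05)
    cand <- cand[pOther > thr, , drop = FALSE]
  }
  if (!nrow(cand))
    stop("no instruments survive tier '", tier, "' for the ", targetPeriod,
         "-period exposure", call. = FALSE)
  new("InstrumentSet", snpIds = cand$snp, weights = cand$beta,
      effectAllele = cand$effect_allele, tier = tier,
      targetPeriod = targetPeriod)
}

# High-tier count for one direction: target-significant SNPs whose
# other-period p-value exceeds 0.05.
.countHighTier <- function(statsTarget, statsOther, gwThreshold) {
  st <- statsTarget
  if (!is.null(st$monomorphic)) st <- st[!st$monomorphic, , drop = FALSE]
  sig <- st[!is.na(st$pval) & st$pval <= gwThreshold, , drop = FALSE]
  pOther <- statsOther$pval[match(sig$snp, statsOther$snp)]
  sum(!is.na(pOther) & pOther > 0.05)
}

#' @rdname computePRS
#' @export
setMethod("computePRS", signature("matrix", "InstrumentSet"),
  function(genotypes, instruments) {
    idx <- match(instruments@snpIds, colnames(genotypes))
    if (anyNA(idx))
      stop("SNP id(s) not found in genotypes: ",
           paste(instruments@snpIds[is.na(idx)], collapse = ", "),
           call. = FALSE)
    drop(genotypes[, idx, drop = FALSE] %*% instruments@weights)
  })

#' @rdname computePRS
#' @export
setMethod("computePRS", signature("LifecourseCohort", "InstrumentSet"),
  function(genotypes, instruments)
    computePRS(genotypeMatrix(genotypes), instruments))

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: %d SNP(s), tier '%s', %s-period target\n",
              length(object@snpIds), object@tier, object@targetPeriod))
  if (length(object@weights))
    cat(sprintf("  |weight| range %.3g-%.3g\n", min(abs(object@weights)),
                max(abs(object@weights))))
})

#' Number of SNPs in an InstrumentSet
#' @param x an \linkS4class{InstrumentSet}.
#' @export
setMethod("length", "InstrumentSet", function(x) length(x@snpIds))

#' Write an InstrumentSet to TSV
#'
#' Columns \code{snp}, \code{weight}, \code{effect_allele}, \code{tier},
#' \code{target_period}, mirroring a supplementary SNP list.
#'
#' @param instruments an \linkS4class{InstrumentSet}.
#' @param path file path.
#' @export
writeInstruments <- function(instruments, path) {
  write.table(
    data.frame(snp = instruments@snpIds, weight = instruments@weights,
               effect_allele = instruments@effectAllele,
               tier = instruments@tier,
               target_period = instruments@targetPeriod),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInstruments
#' @export
readInstruments <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  new("InstrumentSet", snpIds = as.character(tab$snp),
      weights = as.numeric(tab$weight),
      effectAllele = as.character(tab$effect_allele),
      tier = tab$tier[1], targetPeriod = tab$target_period[1])
}
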