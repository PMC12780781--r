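#' @include AllClasses.R
NULL

#' Construct an EstimandRegime from the registry
#'
#' The numeric g-estimator is one formula; which causal contrast it
#' identifies — point, period or lifetime effect in the univariable
#' framework, controlled period effect in the multivariable one — depends
#' only on the assumed timing of the instrument-exposure association.  The
#' registry fixes one assumption text per label so that every estimate
#' carries an explicit, auditable claim.  No separate point-effect estimator
#' is provided: the label exists, but instruments plausibly acting at a
#' single time point are rarely defensible and the univariable arithmetic
#' would be unchanged.
#'
#' @param label one of \code{"point"}, \code{"period"}, \code{"lifetime"},
#'   \code{"controlled-period"}.
#' @return an \linkS4class{EstimandRegime}.
#' @examples
#' estimandRegime("period")
#' @export
estimandRegime <- function(label = c("period", "point", "lifetime",
                                     "controlled-period")) {
  label <- match.arg(label)
  new("EstimandRegime", label = label,
      assumptionText = .estimandRegistry[[label]])
}

#' The full estimand registry
#'
#' @return named character vector mapping each regime label to its
#'   instrument-timing assumption.
#' @export
estimandRegistry <- function() unlist(.estimandRegistry)

setMethod("show", "EstimandRegime", function(object) {
  cat("EstimandRegime:", object@label, "\n")
  cat(strwrap(object@assumptionText, width = 70, prefix = "  "), sep = "\n")
})
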