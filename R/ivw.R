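#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins one or more exposure SummaryStats tables with an outcome
#' table on SNP id and orients every beta to the first table's effect
#' allele: records whose effect/other alleles are swapped have their beta
#' sign flipped; records whose allele pair does not match at all are dropped
#' and reported in the \code{"dropped"} attribute.
#'
#' @param exposureStats a SummaryStats data.frame or a named list of them
#'   (one per exposure).
#' @param outcomeStats a SummaryStats data.frame for the outcome.
#' @return a data.frame with columns \code{snp}, \code{effect_allele},
#'   \code{other_allele}, one \code{bx_<name>} and \code{se_x_<name>} pair
#'   per exposure, and \code{by}, \code{se_y}; dropped SNP ids are in
#'   \code{attr(, "dropped")}.
#' @export
harmonize <- function(exposureStats, outcomeStats) {
  if (is.data.frame(exposureStats)) exposureStats <- list(x = exposureStats)
  if (is.null(names(exposureStats)) || any(names(exposureStats) == ""))
    names(exposureStats) <- paste0("x", seq_along(exposureStats))
  ref <- exposureStats[[1]]
  if (!is.null(ref$monomorphic)) ref <- ref[!ref$monomorphic, , drop = FALSE]
  out <- data.frame(snp = ref$snp, effect_allele = ref$effect_allele,
                    other_allele = ref$other_allele,
                    stringsAsFactors = FALSE)
  dropped <- character()
  alignOne <- function(tab) {
    if (!is.null(tab$monomorphic)) tab <- tab[!tab$monomorphic, , drop = FALSE]
    idx <- match(out$snp, tab$snp)
    beta <- tab$beta[idx]; se <- tab$se[idx]
    same <- tab$effect_allele[idx] == out$effect_allele &
      tab$other_allele[idx] == out$other_allele
    swapped <- tab$effect_allele[idx] == out$other_allele &
      tab$other_allele[idx] == out$effect_allele
    beta[swapped & !is.na(swapped)] <- -beta[swapped & !is.na(swapped)]
    bad <- !is.na(idx) & !(same | swapped)
    beta[bad] <- NA_real_
    dropped <<- union(dropped, out$snp[bad | is.na(idx)])
    list(beta = beta, se = se)
  }
  for (nm in names(exposureStats)) {
    al <- alignOne(exposureStats[[nm]])
    out[[paste0("bx_", nm)]] <- al$beta
    out[[paste0("se_x_", nm)]] <- al$se
  }
  al <- alignOne(outcomeStats)
  out$by <- al$beta
  out$se_y <- al$se
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (!nrow(out))
    stop("no SNPs shared by all summary-statistics tables after ",
         "harmonization", call. = FALSE)
  rownames(out) <- NULL
  if (length(dropped))
    message(length(dropped), " SNP(s) dropped during harmonization: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  attr(out, "dropped") <- dropped
  out
}

#' Inverse-variance-weighted univariable MR
#'
#' Zero-intercept regression of SNP-outcome betas on SNP-exposure betas,
#' each SNP weighted by the inverse variance of its SNP-outcome association:
#' \deqn{\hat\beta = \frac{\sum_j w_j b_{Xj} b_{Yj}}{\sum_j w_j b_{Xj}^2},
#'   \qquad w_j = 1/\mathrm{se}_{Yj}^2.}
#' Cochran's Q of the weighted residuals measures heterogeneity; standard
#' errors are inflated by the multiplicative random-effects scale
#' \code{max(1, sqrt(Q/(J-1)))}.
#'
#' @param bx SNP-exposure betas.
#' @param by SNP-outcome betas.
#' @param seY standard errors of the SNP-outcome betas.
#' @param exposure label for the exposure.
#' @return an \linkS4class{IvwEstimate}.
#' @examples
#' ivwUnivariable(bx = c(1, 2), by = c(1, 1), seY = c(1, 1))  # beta 0.6
#' @export
ivwUnivariable <- function(bx, by, seY, exposure = "x") {
  est <- ivwMvmr(matrix(bx, ncol = 1L, dimnames = list(NULL, exposure)),
                 by, seY)
  est@method <- "ivw-univariable"
  validObject(est)
  est
}

#' Inverse-variance-weighted multivariable MR
#'
#' Weighted least squares of SNP-outcome betas on the K columns of
#' SNP-exposure betas, weights \code{1/seY^2}, no intercept.  Each
#' coefficient is a controlled period effect of its exposure's liability.
#' Q has J - K degrees of freedom and feeds the same multiplicative
#' random-effects scaling as the univariable estimator, to which this
#' reduces exactly when K = 1.
#'
#' @param bxMatrix J-by-K matrix of SNP-exposure betas.
#' @param by SNP-outcome betas (length J).
#' @param seY standard errors of the SNP-outcome betas.
#' @return an \linkS4class{IvwEstimate}.
#' @export
ivwMvmr <- function(bxMatrix, by, seY) {
  B <- as.matrix(bxMatrix)
  by <- as.numeric(by); seY <- as.numeric(seY)
  J <- nrow(B); K <- ncol(B)
  if (length(by) != J || length(seY) != J)
    stop("bxMatrix, by and seY must agree in SNP count", call. = FALSE)
  if (any(seY <= 0)) stop("seY must be positive", call. = FALSE)
  if (J < K + 1L)
    stop("need more SNPs than exposures (J > K)", call. = FALSE)
  if (all(abs(B) < .Machine$double.eps^0.5))
    stop("no instrument relevance: all SNP-exposure betas are zero",
         call. = FALSE)
  w <- 1 / seY^2
  Bw <- B * sqrt(w)
  qrB <- qr(Bw)
  if (qrB$rank < K)
    stop("exposure betas collinear", call. = FALSE)
  XtWX <- crossprod(Bw)
  beta <- drop(solve(XtWX, crossprod(B * w, by)))
  Q <- sum(w * (by - drop(B %*% beta))^2)
  df <- J - K
  reScale <- max(1, sqrt(Q / df))
  se <- sqrt(diag(solve(XtWX))) * reScale
  exposures <- colnames(B)
  if (is.null(exposures)) exposures <- paste0("x", seq_len(K))
  new("IvwEstimate", beta = unname(beta), se = unname(se),
      ciLow = unname(beta - .Z975 * se), ciHigh = unname(beta + .Z975 * se),
      exposures = exposures, heterogeneityQ = Q, df = as.integer(df),
      reScale = reScale, method = "ivw-mvmr", nSnps = as.integer(J))
}

setMethod("show", "IvwEstimate", function(object) {
  cat(sprintf("IvwEstimate (%s), %d SNPs; Q = %.3g on %d df (RE scale %.3g)\n",
              object@method, object@nSnps, object@heterogeneityQ, object@df,
              object@reScale))
  df <- data.frame(exposure = object@exposures,
                   beta = signif(object@beta, 4),
                   se = signif(object@se, 4),
                   ci95 = sprintf("[%.4g, %.4g]", object@ciLow,
                                  object@ciHigh))
  print(df, row.names = FALSE)
})

#' @describeIn lifecourseAccessors point estimate(s).
#' @export
setMethod("estimate", "IvwEstimate", function(object) {
  names(object@beta) <- object@exposures
  object@beta
})

#' @describeIn lifecourseAccessors standard error(s).
#' @export
setMethod("stdError", "IvwEstimate", function(object) {
  names(object@se) <- object@exposures
  object@se
})

#' @describeIn lifecourseAccessors 95\% confidence limits.
#' @export
setMethod("confInt", "IvwEstimate", function(object)
  cbind(low = object@ciLow, high = object@ciHigh))
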