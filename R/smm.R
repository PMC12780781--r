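#' @include AllClasses.R AllGenerics.R utils.R estimands.R
NULL

# Shared input handling: equal lengths, optional covariate residualization.
.smmPrepare <- function(z, x, y, covariates) {
  z <- as.matrix(z); x <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (nrow(z) != n || nrow(x) != n)
    stop("z, x and y must have the same number of rows", call. = FALSE)
  if (anyNA(z) || anyNA(x) || anyNA(y))
    stop("missing values in z, x or y; filter complete cases first",
         call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    z <- residualizeOn(z, covariates)
    x <- residualizeOn(x, covariates)
    y <- drop(residualizeOn(y, covariates))
  }
  list(z = z, x = x, y = y, n = n)
}

#' Univariable additive structural mean model by g-estimation
#'
#' Solves the estimating equation
#' \deqn{\sum_i (z_i - \bar z)(y_i - \psi x_i) = 0,}
#' i.e. the instrument is forced to be uncorrelated with the residual of the
#' counterfactual outcome.  The solution is the Wald ratio
#' \eqn{\hat\psi = \mathrm{cov}(z, y) / \mathrm{cov}(z, x)}, a risk
#' difference per unit of exposure when \code{y} is binary.  Whether the
#' estimate is a point, period or lifetime effect depends only on the
#' instrument-timing assumption recorded in the \code{regime}; the
#' arithmetic is identical.
#'
#' @param z instrument (typically a polygenic risk score).
#' @param x exposure.
#' @param y outcome; binary gives a risk-difference contrast, a non-binary
#'   outcome is accepted but flagged.
#' @param covariates optional matrix; when supplied, z, x and y are
#'   residualized on it before estimation.
#' @param seMethod \code{"sandwich"} (default) or \code{"bootstrap"}.
#' @param regime estimand regime label claimed for the estimate
#'   (default \code{"period"}).
#' @param exposure label for the exposure.
#' @param nBoot,seed bootstrap controls when \code{seMethod = "bootstrap"}.
#' @return an \linkS4class{SmmEstimate} with the first-stage F statistic of
#'   the exposure on the instrument as a relevance diagnostic.
#' @examples
#' smmUnivariable(z = c(0, 0, 1, 1), x = c(1, 1, 2, 2), y = c(0, 0, 1, 1))
#' @export
smmUnivariable <- function(z, x, y, covariates = NULL,
                           seMethod = c("sandwich", "bootstrap"),
                           regime = "period", exposure = "x",
                           nBoot = 1000L, seed = 1L) {
  seMethod <- match.arg(seMethod)
  d <- .smmPrepare(z, x, y, covariates)
  if (ncol(d$z) != 1L || ncol(d$x) != 1L)
    stop("smmUnivariable takes a single instrument and a single exposure",
         call. = FALSE)
  zv <- drop(d$z); xv <- drop(d$x); yv <- d$y; n <- d$n
  if (sd(zv) == 0)
    stop("no instrument relevance: the instrument is constant",
         call. = FALSE)
  if (any(!(yv %in% c(0, 1))))
    message("non-binary outcome: estimates are mean differences, ",
            "not risk differences")
  zc <- zv - mean(zv)
  denom <- sum(zc * xv)
  tol <- 1e-12 * n * sd(zv) * sd(xv)
  if (abs(denom) <= tol)
    stop("no instrument relevance: instrument-exposure covariance is zero ",
         "within tolerance", call. = FALSE)
  psi <- sum(zc * yv) / denom
  r2 <- cor(zv, xv)^2
  fStat <- r2 / (1 - r2) * (n - 2)
  .finishSmm(psi = psi, zEff = matrix(zv), x = matrix(xv), y = yv,
             method = "smm-univariable", seMethod = seMethod,
             regime = regime, exposures = exposure, fStat = fStat,
             nBoot = nBoot, seed = seed,
             refit = function(zz, xx, yy) {
               zzc <- zz[, 1L] - mean(zz[, 1L])
               sum(zzc * yy) / sum(zzc * xx[, 1L])
             })
}

#' Multivariable additive structural mean model by g-estimation
#'
#' Solves the stacked moment conditions
#' \eqn{E[(Z - E Z)(Y - X^\top\psi)] = 0} for K exposures instrumented by M
#' instruments.  Just-identified systems (M = K) are solved directly from
#' the instrument-exposure cross-covariance; over-identified systems (M > K)
#' project each exposure on all instruments first and solve with the fitted
#' values (the two-stage least-squares weighting).  Estimates are controlled
#' period effects: each exposure's effect with the others held fixed.
#'
#' @param zMatrix n-by-M instrument matrix (e.g. one polygenic score per
#'   period).
#' @param xMatrix n-by-K exposure matrix.
#' @param y outcome.
#' @param covariates,seMethod,nBoot,seed as in [smmUnivariable()].
#' @param regime estimand regime label (default \code{"controlled-period"}).
#' @return an \linkS4class{SmmEstimate} with conditional F statistics (each
#'   exposure residualized on the others, regressed on all instruments) as
#'   instrument-strength diagnostics.
#' @examples
#' tr <- defaultSimulationTruth(seed = 5, nIndividuals = 2000)
#' coh <- generateCohort(tr)
#' g <- genotypeMatrix(coh)
#' zE <- g[, periodSpecificSnps(tr, "early")] %*%
#'   tr@alpha1[periodSpecificSnps(tr, "early")]
#' zL <- g[, periodSpecificSnps(tr, "late")] %*%
#'   tr@alpha2[periodSpecificSnps(tr, "late")]
#' smmMultivariable(cbind(zE, zL),
#'                  cbind(x1 = colData(coh)$x1, x2 = colData(coh)$x2),
#'                  colData(coh)$y)
#' @export
smmMultivariable <- function(zMatrix, xMatrix, y, covariates = NULL,
                             seMethod = c("sandwich", "bootstrap"),
                             regime = "controlled-period",
                             nBoot = 1000L, seed = 1L) {
  seMethod <- match.arg(seMethod)
  d <- .smmPrepare(zMatrix, xMatrix, y, covariates)
  Z <- d$z; X <- d$x; yv <- d$y; n <- d$n
  M <- ncol(Z); K <- ncol(X)
  if (M < K)
    stop("need at least as many instruments as exposures (M >= K)",
         call. = FALSE)
  exposures <- colnames(X)
  if (is.null(exposures)) exposures <- paste0("x", seq_len(K))
  solveCore <- function(Z, X, yv) {
    # Over-identified: two-stage projection; the fitted exposures become the
    # just-identified instrument set.
    zEff <- if (ncol(Z) > ncol(X)) qr.fitted(qr(cbind(1, Z)), X) else Z
    Zc <- scale(zEff, center = TRUE, scale = FALSE)
    SZX <- crossprod(Zc, X) / nrow(X)
    sv <- svd(SZX, nu = 0, nv = 0)$d
    if (sv[1] == 0 || sv[1] / sv[length(sv)] > 1e10)
      stop("instruments do not separate exposures: cross-covariance ",
           "matrix is singular", call. = FALSE)
    sZY <- crossprod(Zc, yv) / nrow(X)
    list(psi = drop(solve(SZX, sZY)), zEff = zEff)
  }
  core <- solveCore(Z, X, yv)
  fStat <- vapply(seq_len(K), function(k) {
    xt <- if (K > 1L) drop(residualizeOn(X[, k], X[, -k, drop = FALSE]))
          else X[, k] - mean(X[, k])
    ft <- qr.fitted(qr(cbind(1, Z)), xt)
    r2 <- sum((ft - mean(ft))^2) / sum((xt - mean(xt))^2)
    (r2 / M) / ((1 - r2) / (n - M - 1))
  }, numeric(1))
  .finishSmm(psi = core$psi, zEff = core$zEff, x = X, y = yv,
             method = "smm-multivariable", seMethod = seMethod,
             regime = regime, exposures = exposures, fStat = fStat,
             nBoot = nBoot, seed = seed,
             refit = function(zz, xx, yy) solveCore(zz, xx, yy)$psi)
}

# Assemble the SmmEstimate: sandwich or bootstrap inference around psi.
.finishSmm <- function(psi, zEff, x, y, method, seMethod, regime, exposures,
                       fStat, nBoot, seed, refit) {
  if (seMethod == "sandwich") {
    se <- as.numeric(sandwichSE(zEff, x, y, psi))
    ciLow <- psi - .Z975 * se
    ciHigh <- psi + .Z975 * se
  } else {
    bt <- bootstrapSE(function(d) refit(d$z, d$x, d$y),
                      list(z = zEff, x = x, y = y),
                      nBoot = nBoot, seed = seed)
    se <- bt$se
    ciLow <- pmin(bt$ciLow, psi)
    ciHigh <- pmax(bt$ciHigh, psi)
  }
  new("SmmEstimate", psi = unname(psi), se = unname(se),
      ciLow = unname(ciLow), ciHigh = unname(ciHigh),
      exposures = exposures, method = method, seMethod = seMethod,
      regime = estimandRegime(regime), nUsed = length(y),
      firstStageF = unname(fStat))
}

#' Sandwich variance of the g-estimated structural mean model
#'
#' With moment contributions \eqn{g_i(\psi) = (Z_i - \bar Z)(y_i -
#' X_i^\top\psi)}, the estimator variance is
#' \eqn{A^{-1} B A^{-\top} / n} where
#' \eqn{A = n^{-1}\sum (Z_i - \bar Z) X_i^\top} and
#' \eqn{B = n^{-1}\sum g_i g_i^\top}.
#'
#' @param zMatrix n-by-K instrument matrix (fitted exposures in the
#'   over-identified case).
#' @param xMatrix n-by-K exposure matrix.
#' @param y outcome vector.
#' @param psiHat the point estimate the residuals are formed with.
#' @return vector of standard errors, with the full covariance matrix in
#'   attribute \code{"vcov"}.
#' @export
sandwichSE <- function(zMatrix, xMatrix, y, psiHat) {
  Z <- as.matrix(zMatrix); X <- as.matrix(xMatrix); y <- as.numeric(y)
  n <- length(y)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  A <- crossprod(Zc, X) / n
  # the baseline of the additive SMM is estimated alongside psi, so the
  # moment residual is centered; leaving its mean in would overstate B and
  # give conservative intervals
  resid <- y - drop(X %*% psiHat)
  G <- Zc * (resid - mean(resid))
  B <- crossprod(G) / n
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("instruments do not separate exposures: cross-covariance matrix ",
         "is singular", call. = FALSE))
  V <- Ainv %*% B %*% t(Ainv) / n
  se <- sqrt(pmax(diag(V), 0))
  attr(se, "vcov") <- V
  se
}

#' Nonparametric case-resampling bootstrap for an estimator
#'
#' Resamples individuals with replacement, re-applies the estimator, and
#' summarizes the replicate estimates by their standard deviation and
#' percentile 95\% interval.  Deterministic given \code{seed}.  Replicates
#' that fail (e.g. singular resamples) are dropped; more than 10\% failures
#' is an error.
#'
#' @param estimator function taking the data object and returning a numeric
#'   vector of estimates.
#' @param data a list or data.frame whose elements share the same number of
#'   rows (individuals).
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return list with \code{se}, \code{ciLow}, \code{ciHigh} (percentile),
#'   \code{nFailed} and the replicate matrix \code{estimates}.
#' @export
bootstrapSE <- function(estimator, data, nBoot = 1000L, seed = 1L) {
  if (nBoot < 100L) stop("nBoot must be >= 100", call. = FALSE)
  n <- NROW(data[[1]])
  resampleRow <- function(el, idx)
    if (is.matrix(el) || is.data.frame(el)) el[idx, , drop = FALSE]
    else el[idx]
  reps <- withSeed(seed, {
    lapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(estimator(lapply(data, resampleRow, idx = idx)),
               error = function(e) NULL)
    })
  })
  failed <- vapply(reps, is.null, logical(1))
  if (mean(failed) > 0.10)
    stop(sprintf("%.0f%% of bootstrap replicates failed", 100 * mean(failed)),
         call. = FALSE)
  est <- do.call(rbind, reps[!failed])
  list(se = apply(est, 2L, sd),
       ciLow = apply(est, 2L, quantile, probs = 0.025, names = FALSE),
       ciHigh = apply(est, 2L, quantile, probs = 0.975, names = FALSE),
       nFailed = sum(failed), estimates = est)
}

setMethod("show", "SmmEstimate", function(object) {
  cat(sprintf("SmmEstimate (%s, %s SEs, %s regime), n = %d\n",
              object@method, object@seMethod, object@regime@label,
              object@nUsed))
  df <- data.frame(exposure = object@exposures,
                   psi = signif(object@psi, 4),
                   se = signif(object@se, 4),
                   ci95 = sprintf("[%.4g, %.4g]", object@ciLow,
                                  object@ciHigh),
                   F = signif(object@firstStageF, 4))
  print(df, row.names = FALSE)
})

#' @describeIn lifecourseAccessors point estimate(s).
#' @export
setMethod("estimate", "SmmEstimate", function(object) {
  names(object@psi) <- object@exposures
  object@psi
})

#' @describeIn lifecourseAccessors standard error(s).
#' @export
setMethod("stdError", "SmmEstimate", function(object) {
  names(object@se) <- object@exposures
  object@se
})

#' Accessors for estimate objects
#'
#' @param object an \linkS4class{SmmEstimate} or \linkS4class{IvwEstimate}.
#' @name lifecourseAccessors
#' @describeIn lifecourseAccessors 95\% confidence limits as a two-column
#'   matrix.
#' @export
setMethod("confInt", "SmmEstimate", function(object)
  cbind(low = object@ciLow, high = object@ciHigh))

#' @describeIn lifecourseAccessors the claimed estimand regime.
#' @export
setMethod("regime", "SmmEstimate", function(object) object@regime)

#' @describeIn lifecourseAccessors first-stage instrument-strength
#'   diagnostics.
#' @export
setMethod("firstStageF", "SmmEstimate", function(object) {
  names(object@firstStageF) <- object@exposures
  object@firstStageF
})
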