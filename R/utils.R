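# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Residuals of the columns of `m` (vector or matrix) on an intercept plus
# optional covariate columns.
residualizeOn <- function(m, covariates = NULL) {
  m <- as.matrix(m)
  W <- if (is.null(covariates)) matrix(1, nrow(m), 1L)
       else cbind(1, as.matrix(covariates))
  qr.resid(qr(W), m)
}

# 97.5% normal quantile used for all sandwich-type confidence intervals.
.Z975 <- 1.959964

.assertScalarProb <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop(what, " must be a probability strictly in (0,1)", call. = FALSE)
  invisible(x)
}
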