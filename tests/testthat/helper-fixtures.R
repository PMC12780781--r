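# Shared fixtures: built in code, no files on disk.

# Hand-assembled summary statistics in the package TSV dialect.
makeStats <- function(snp, pval, beta = rep(0.1, length(snp)),
                      se = rep(0.01, length(snp)),
                      ea = rep("A", length(snp)),
                      oa = rep("G", length(snp)), n = 1000L) {
  out <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                    beta = beta, se = se, pval = pval, n = n,
                    monomorphic = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("SummaryStats", "data.frame")
  out
}

# Small fast truth for unit tests: 4 early, 4 late, 2 shared SNPs.
tinyTruth <- function(seed = 1L, n = 600L, ...) {
  defaultSimulationTruth(seed = seed, nIndividuals = n, nEarly = 4L,
                         nLate = 4L, nShared = 2L, ...)
}

# Independent naive two-stage least-squares oracle: two lm() fits, nothing
# shared with the package estimator path.
tslsOracle <- function(Z, X, y) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  Xhat <- sapply(seq_len(ncol(X)),
                 function(k) fitted(lm(X[, k] ~ Z)))
  unname(coef(lm(y ~ Xhat))[-1])
}

# Oracle period-specific polygenic scores built from the generating truth.
oraclePrs <- function(cohort, truth) {
  g <- genotypeMatrix(cohort)
  e <- periodSpecificSnps(truth, "early")
  l <- periodSpecificSnps(truth, "late")
  list(early = drop(g[, e, drop = FALSE] %*% truth@alpha1[e]),
       late = drop(g[, l, drop = FALSE] %*% truth@alpha2[l]))
}
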