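test_that("harmonization aligns, flips and drops alleles correctly", {
  ex <- makeStats(c("rs1", "rs2", "rs3"), pval = rep(1e-9, 3),
                  beta = c(0.1, 0.2, 0.3))
  # rs1 identical coding, rs2 swapped alleles, rs3 incompatible pair
  out <- makeStats(c("rs1", "rs2", "rs3"), pval = rep(0.5, 3),
                   beta = c(0.05, 0.2, 0.4),
                   ea = c("A", "G", "C"), oa = c("G", "A", "T"))
  h <- suppressMessages(harmonize(ex, out))
  expect_identical(h$snp, c("rs1", "rs2"))
  expect_equal(h$by, c(0.05, -0.2))
  expect_true("rs3" %in% attr(h, "dropped"))

  # identical coding everywhere: an identity join
  h2 <- harmonize(ex, makeStats(c("rs1", "rs2", "rs3"), pval = rep(0.5, 3),
                                beta = c(1, 2, 3)))
  expect_identical(nrow(h2), 3L)
  expect_equal(h2$by, c(1, 2, 3))

  expect_error(harmonize(ex, makeStats("rs9", pval = 0.5)), "no SNPs")
})

test_that("IVW univariable matches the weighted closed form", {
  e1 <- ivwUnivariable(bx = c(1, 1), by = c(0.5, 0.5), seY = c(1, 1))
  expect_equal(e1@beta, 0.5)
  expect_equal(e1@heterogeneityQ, 0)

  e2 <- ivwUnivariable(bx = c(1, 2), by = c(1, 1), seY = c(1, 1))
  expect_equal(e2@beta, 0.6)

  # exact proportionality recovers the constant with zero heterogeneity,
  # whatever the weights
  set.seed(11)
  bx <- rnorm(20); seY <- runif(20, 0.5, 2)
  e3 <- ivwUnivariable(bx, by = -1.7 * bx, seY = seY)
  expect_equal(e3@beta, -1.7, tolerance = 1e-12)
  expect_equal(e3@heterogeneityQ, 0, tolerance = 1e-18)
  expect_equal(e3@reScale, 1)

  expect_error(ivwUnivariable(1, 0.5, 1), "J > K")
  expect_error(ivwUnivariable(c(0, 0), c(0.5, 0.2), c(1, 1)), "relevance")
})

test_that("IVW-MVMR is weighted least squares without intercept", {
  set.seed(12)
  J <- 50
  B <- cbind(rnorm(J), rnorm(J))
  by <- drop(B %*% c(0.4, -0.1)) + rnorm(J, sd = 0.05)
  seY <- runif(J, 0.05, 0.2)
  est <- ivwMvmr(B, by, seY)
  # independent oracle: explicit weighted normal equations
  W <- diag(1 / seY^2)
  betaHand <- solve(t(B) %*% W %*% B, t(B) %*% W %*% by)
  expect_lt(max(abs(est@beta - drop(betaHand))), 1e-10)
  expect_identical(est@df, 48L)

  # K = 1 reduces exactly to the univariable estimator
  uni <- ivwUnivariable(B[, 1], by, seY)
  mv1 <- ivwMvmr(B[, 1, drop = FALSE], by, seY)
  expect_equal(uni@beta, mv1@beta, tolerance = 1e-14)
  expect_equal(uni@se, mv1@se, tolerance = 1e-14)
  expect_equal(uni@heterogeneityQ, mv1@heterogeneityQ, tolerance = 1e-10)

  # outcome betas in the exposure-beta span: exact recovery, Q = 0
  byExact <- drop(B %*% c(1.5, -2))
  ex <- ivwMvmr(B, byExact, seY)
  expect_equal(ex@beta, c(1.5, -2), tolerance = 1e-10)
  expect_lt(ex@heterogeneityQ, 1e-16)

  expect_error(ivwMvmr(cbind(B[, 1], B[, 1]), by, seY), "collinear")
})

test_that("random-effects scaling floors at 1 and inflates under
           heterogeneity", {
  set.seed(13)
  bx <- rnorm(30, 1, 0.2)
  byHet <- 0.5 * bx + rnorm(30, sd = 0.5)   # far larger than seY = 0.01
  est <- ivwUnivariable(bx, byHet, seY = rep(0.01, 30))
  expect_gt(est@reScale, 1)
  expect_equal(est@reScale, sqrt(est@heterogeneityQ / est@df))
})

test_that("one-sample overlap biases weak-instrument IVW toward the
           confounded association", {
  # null causal effect, strong confounding, very weak instruments: with
  # fully overlapping discovery and outcome samples the estimate leans
  # toward the observational slope; splitting the samples removes this
  nRep <- 30
  one <- split <- numeric(nRep)
  for (r in seq_len(nRep)) {
    tr <- defaultSimulationTruth(seed = 7000 + r, nIndividuals = 3000,
                                 nEarly = 50L, nLate = 0L, nShared = 0L,
                                 effectSizeRange = c(0.005, 0.02),
                                 theta = 0, confLoadX1 = 0.7,
                                 confLoadX2 = 0, confLoadY = 0.1,
                                 psi1 = 0, psi2 = 0)
    coh <- generateCohort(tr)
    sFullX <- assocScan(coh, "x1")
    sFullY <- assocScan(coh, "y")
    one[r] <- ivwUnivariable(sFullX$beta, sFullY$beta, sFullY$se)@beta
    a <- coh[, 1:1500]; b <- coh[, 1501:3000]
    sHalfX <- assocScan(a, "x1")
    sHalfY <- assocScan(b, "y")
    split[r] <- ivwUnivariable(sHalfX$beta, sHalfY$beta, sHalfY$se)@beta
  }
  d <- one - split
  tStat <- mean(d) / (sd(d) / sqrt(nRep))
  expect_gt(tStat, 2)            # overlap bias is systematically positive
  expect_gt(mean(one), 0)        # and points toward the confounded slope
})
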