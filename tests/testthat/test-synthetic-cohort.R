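test_that("genotype simulation honours allele-frequency bounds and moments", {
  expect_error(generateGenotypes(c(0.2, 1.2), n = 5, seed = 1), "maf")
  expect_error(generateGenotypes(-0.1, n = 5, seed = 1), "maf")

  # degenerate frequencies are allowed at the matrix level and fix the column
  expect_true(all(generateGenotypes(0, n = 5, seed = 1) == 0L))
  expect_true(all(generateGenotypes(1, n = 5, seed = 1) == 2L))

  g <- generateGenotypes(0.5, n = 10000, seed = 42)
  seMean <- sqrt(2 * 0.25 / 10000)
  expect_lt(abs(mean(g) - 1), 3 * seMean)

  expect_identical(generateGenotypes(c(0.2, 0.4), n = 50, seed = 7),
                   generateGenotypes(c(0.2, 0.4), n = 50, seed = 7))
})

test_that("3-tier recoding splits by floor arithmetic with stable ties", {
  t1 <- categorizeThreeTier(1:10, c(0.3, 0.4, 0.3))
  expect_identical(as.integer(table(t1)), c(3L, 4L, 3L))
  expect_identical(as.character(t1[1:3]), rep("thinner", 3))

  # all-equal values: the stable original-order tie-break still yields the
  # exact split, earliest entries in the lowest tier
  t2 <- categorizeThreeTier(rep(5, 10), c(0.3, 0.4, 0.3))
  expect_identical(as.integer(table(t2)), c(3L, 4L, 3L))
  expect_identical(as.character(t2[1:3]), rep("thinner", 3))
  expect_identical(as.character(t2[8:10]), rep("plumper", 3))

  set.seed(1)
  t3 <- categorizeThreeTier(rank(rnorm(1000)), rep(1, 3) / 3)
  expect_identical(as.integer(table(t3)), c(333L, 333L, 334L))

  expect_error(categorizeThreeTier(1:2, rep(1, 3) / 3), "at least 3")
  expect_error(categorizeThreeTier(c(1, NA, 3), rep(1, 3) / 3), "missing")
})

test_that("cohort generation is deterministic and reports clamping", {
  tr <- tinyTruth(seed = 3, n = 400)
  c1 <- generateCohort(tr)
  c2 <- generateCohort(tr)
  expect_identical(assay(c1, "genotypes"), assay(c2, "genotypes"))
  expect_identical(colData(c1), colData(c2))
  expect_identical(clampFraction(c1), clampFraction(c2))
  expect_true(clampFraction(c1) >= 0)

  # a huge effect forces heavy clamping: warning, error in strict mode
  bad <- tinyTruth(seed = 3, n = 400, psi2 = 0.9)
  expect_warning(generateCohort(bad), "clamped")
  expect_error(generateCohort(bad, strict = TRUE), "clamped")
})

test_that("null outcome model reproduces the baseline risk", {
  tr <- tinyTruth(seed = 8, n = 20000, psi1 = 0, psi2 = 0, confLoadY = 0,
                  baselineRisk = 0.3)
  coh <- generateCohort(tr)
  y <- colData(coh)$y
  expect_lt(abs(mean(y) - 0.3), 3 * sqrt(0.3 * 0.7 / length(y)))
})

test_that("exposure variance matches the generating covariance algebra", {
  tr <- defaultSimulationTruth(seed = 15, nIndividuals = 50000)
  coh <- generateCohort(tr)
  x1 <- colData(coh)$x1
  gvar <- sum(tr@alpha1^2 * 2 * tr@maf * (1 - tr@maf))
  expected <- gvar + tr@confLoadX1^2 + tr@sigma1^2
  # Monte-Carlo tolerance: var of the sample variance ~ 2 sigma^4 / n
  tol <- 4 * sqrt(2 / 50000) * expected
  expect_lt(abs(var(x1) - expected), tol)
})

test_that("least squares on (x1, x2) recovers psi under no confounding", {
  tr <- defaultSimulationTruth(seed = 21, nIndividuals = 30000,
                               confLoadY = 0)
  coh <- generateCohort(tr)
  cd <- colData(coh)
  fit <- summary(lm(y ~ x1 + x2, data = as.data.frame(cd)))$coefficients
  expect_lt(abs(fit["x1", 1] - tr@psi1), 3 * fit["x1", 2])
  expect_lt(abs(fit["x2", 1] - tr@psi2), 3 * fit["x2", 2])
})

test_that("tier proportions are realized exactly up to integer rounding", {
  tr <- tinyTruth(seed = 5, n = 1000,
                  tierProportions = c(0.25, 0.5, 0.25))
  coh <- generateCohort(tr)
  expect_identical(as.integer(table(colData(coh)$x1Tier)),
                   c(250L, 500L, 250L))
  expect_identical(as.integer(table(colData(coh)$x2Tier)),
                   c(250L, 500L, 250L))
})

test_that("complete-case filtering drops and counts the right rows", {
  g <- generateGenotypes(c(0.3, 0.4), n = 10, seed = 2)
  x1 <- rnorm(10); x2 <- rnorm(10); y <- rbinom(10, 1, 0.5)
  x2[c(3, 7)] <- NA
  coh <- lifecourseCohort(g, x1, x2, y)
  expect_message(out <- filterCompleteCases(coh), "8 of 10")
  expect_identical(ncol(out), 8L)
  expect_false(anyNA(colData(out)$x2))

  full <- lifecourseCohort(g, rnorm(10), rnorm(10), rbinom(10, 1, 0.5))
  expect_identical(ncol(filterCompleteCases(full, quiet = TRUE)), 10L)

  none <- lifecourseCohort(g, rep(NA_real_, 10), rnorm(10),
                           rbinom(10, 1, 0.5))
  expect_error(filterCompleteCases(none), "complete")
})

test_that("observed view hides the confounder and the truth", {
  coh <- generateCohort(tinyTruth(seed = 9, n = 100))
  expect_true("u" %in% colnames(colData(coh)))
  expect_s4_class(simTruth(coh), "SimulationTruth")
  obs <- observedCohort(coh)
  expect_false("u" %in% colnames(colData(obs)))
  expect_null(simTruth(obs))
  # the observed data themselves are untouched
  expect_identical(colData(obs)$x1, colData(coh)$x1)
})

test_that("truth invariants are enforced and derived effect is exposed", {
  expect_error(simulationTruth(10, maf = c(0.2, 1.5), alpha1 = c(0, 0),
                               alpha2 = c(0, 0)), "maf")
  expect_error(tinyTruth(tierProportions = c(0.5, 0.4, 0.2)),
               "tierProportions")
  tr <- tinyTruth(psi1 = -0.02, psi2 = 0.1, theta = 0.6)
  expect_equal(trueTotalEarlyEffect(tr), -0.02 + 0.6 * 0.1)
})
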