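test_that("univariable g-estimation solves the closed form", {
  est <- smmUnivariable(z = c(0, 0, 1, 1), x = c(1, 1, 2, 2),
                        y = c(0, 0, 1, 1))
  expect_equal(est@psi, 1.0, tolerance = 1e-12)
  expect_s4_class(est, "SmmEstimate")
  expect_identical(est@regime@label, "period")

  # constant outcome: the numerator vanishes
  estNull <- smmUnivariable(c(0, 1, 0, 1), c(1, 2, 1.5, 2.5), rep(1, 4))
  expect_equal(estNull@psi, 0)

  # constant instrument, and exactly orthogonal instrument-exposure pair
  expect_error(smmUnivariable(rep(1, 4), c(1, 2, 1, 2), c(0, 1, 0, 1)),
               "relevance")
  expect_error(smmUnivariable(c(-1, 1, -1, 1), c(1, 1, 2, 2),
                              c(0, 1, 0, 1)), "relevance")
  expect_message(smmUnivariable(c(0, 1, 2, 3), c(1, 2, 3, 4),
                                c(0.1, 0.4, 0.2, 0.9)), "non-binary")
})

test_that("univariable estimate equals the Wald ratio and ignores
           instrument scale", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- rbinom(n, 1, 0.5)
    est <- smmUnivariable(z, x, y)
    expect_equal(est@psi, cov(z, y) / cov(z, x), tolerance = 1e-12)
    est2 <- smmUnivariable(z * 17.3, x, y)
    expect_equal(est2@psi, est@psi, tolerance = 1e-12)
  }
})

test_that("multivariable estimator solves the moment conditions", {
  set.seed(303)
  n <- 400
  Z <- matrix(rnorm(2 * n), n, 2)
  X <- Z %*% matrix(c(0.8, 0.1, 0.2, 0.9), 2) + matrix(rnorm(2 * n), n, 2)
  y <- rbinom(n, 1, plogis(X %*% c(0.3, -0.2)))
  est <- smmMultivariable(Z, X, y)
  Zc <- scale(Z, scale = FALSE)
  psiHand <- solve(crossprod(Zc, X), crossprod(Zc, y))
  expect_equal(est@psi, drop(psiHand), tolerance = 1e-12)

  # duplicate exposure columns cannot be separated
  expect_error(smmMultivariable(Z, cbind(X[, 1], X[, 1]), y), "separate")
  # more exposures than instruments is rejected
  expect_error(smmMultivariable(Z[, 1, drop = FALSE], X, y), "M >= K")
})

test_that("just- and over-identified fits match a naive 2SLS oracle", {
  set.seed(404)
  for (M in c(2L, 5L)) {
    n <- 300
    Z <- matrix(rnorm(M * n), n, M)
    A <- matrix(rnorm(2 * M, sd = 0.6), M, 2)
    X <- Z %*% A + matrix(rnorm(2 * n), n, 2)
    y <- drop(X %*% c(0.25, -0.15)) + rnorm(n)
    est <- suppressMessages(smmMultivariable(Z, X, y))
    oracle <- tslsOracle(Z, X, y)
    expect_lt(max(abs(est@psi - oracle) / abs(oracle)), 1e-10)
  }
})

test_that("sandwich variance has the right degenerate and scaling
           behaviour", {
  set.seed(505)
  n <- 200
  z <- rnorm(n); x <- z + rnorm(n)
  psi <- 0.4
  yExact <- psi * x                      # zero residual everywhere
  expect_equal(sandwichSE(matrix(z), matrix(x), yExact, psi)[1], 0,
               tolerance = 1e-12, ignore_attr = TRUE)

  y <- rbinom(n, 1, 0.4)
  est <- suppressMessages(smmUnivariable(z, x, y))
  se1 <- est@se
  est2 <- suppressMessages(smmUnivariable(rep(z, 2), rep(x, 2), rep(y, 2)))
  expect_equal(est2@se, se1 / sqrt(2), tolerance = 1e-10)
})

test_that("bootstrap inference is deterministic and sane", {
  set.seed(606)
  n <- 400
  z <- rnorm(n); x <- z + rnorm(n); y <- rbinom(n, 1, plogis(0.3 * x))
  b1 <- smmUnivariable(z, x, y, seMethod = "bootstrap", nBoot = 300,
                       seed = 42)
  b2 <- smmUnivariable(z, x, y, seMethod = "bootstrap", nBoot = 300,
                       seed = 42)
  expect_identical(b1@se, b2@se)
  expect_identical(b1@ciLow, b2@ciLow)

  # on well-behaved data the bootstrap agrees with the sandwich
  s <- smmUnivariable(z, x, y)
  b3 <- smmUnivariable(z, x, y, seMethod = "bootstrap", nBoot = 2000,
                       seed = 7)
  expect_lt(abs(b3@se - s@se) / s@se, 0.15)

  expect_error(bootstrapSE(function(d) stop("boom"),
                           list(z = z, x = x, y = y), nBoot = 100,
                           seed = 1), "failed")
  expect_error(bootstrapSE(function(d) 1, list(z = z), nBoot = 50,
                           seed = 1), "nBoot")
})

test_that("covariate residualization matches manual pre-adjustment", {
  set.seed(707)
  n <- 500
  cov1 <- rnorm(n); cov2 <- rbinom(n, 1, 0.5)
  z <- rnorm(n) + 0.5 * cov1
  x <- z + rnorm(n) + cov2
  y <- rbinom(n, 1, 0.4)
  W <- cbind(cov1, cov2)
  est <- suppressMessages(smmUnivariable(z, x, y, covariates = W))
  rz <- residuals(lm(z ~ W)); rx <- residuals(lm(x ~ W))
  ry <- residuals(lm(y ~ W))
  manual <- suppressMessages(smmUnivariable(rz, rx, ry))
  expect_equal(est@psi, manual@psi, tolerance = 1e-10)
})

test_that("estimate accessors expose psi, SEs, CIs and F statistics", {
  est <- suppressMessages(
    smmUnivariable(rnorm(100), rnorm(100) + 1, rbinom(100, 1, 0.5),
                   exposure = "early"))
  expect_named(estimate(est), "early")
  expect_named(stdError(est), "early")
  ci <- confInt(est)
  expect_true(ci[, "low"] <= estimate(est) &&
                estimate(est) <= ci[, "high"])
  expect_identical(regime(est)@label, "period")
  expect_true(firstStageF(est) >= 0)
})
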