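test_that("Bonferroni threshold pools the period-specific counts", {
  expect_identical(bonferroniThreshold(55, 218), 0.05 / 273)
  expect_identical(bonferroniThreshold(1, 0), 0.05)
  expect_error(bonferroniThreshold(0, 0), "at least one")
  expect_error(bonferroniThreshold(-1, 2), "nonnegative")
})

test_that("tier rules retain and exclude SNPs as specified", {
  # strongly target-associated, weakly other-associated: kept everywhere
  stT <- makeStats("rs1", pval = 1e-9)
  stO <- makeStats("rs1", pval = 0.2)
  for (tier in c("low", "low-medium", "medium-high", "high"))
    expect_identical(
      selectInstruments(stT, stO, tier, bonferroni = 1e-3)@snpIds, "rs1")

  # strongly associated with both: only the low tier keeps it
  stO2 <- makeStats("rs1", pval = 1e-10)
  expect_identical(selectInstruments(stT, stO2, "low")@snpIds, "rs1")
  for (tier in c("low-medium", "medium-high", "high"))
    expect_error(
      selectInstruments(stT, stO2, tier, bonferroni = 1e-3), tier)

  # three-SNP example: only rs1 survives the high tier
  stT3 <- makeStats(c("rs1", "rs2", "rs3"), pval = c(1e-9, 1e-9, 1e-3))
  stO3 <- makeStats(c("rs1", "rs2", "rs3"), pval = c(0.2, 0.01, 0.2))
  high <- selectInstruments(stT3, stO3, "high")
  expect_identical(high@snpIds, "rs1")

  # retention needs p_other strictly greater than the exclusion threshold
  stEq <- makeStats("rs1", pval = 0.05)
  expect_error(selectInstruments(stT, stEq, "high"), "high")

  # a candidate with no other-period record is an error
  stO4 <- makeStats("rsX", pval = 0.5)
  expect_error(selectInstruments(stT, stO4, "high"), "rs1")
})

test_that("instrument sets are nested with increasing stringency", {
  coh <- generateCohort(defaultSimulationTruth(seed = 31,
                                               nIndividuals = 10000,
                                               theta = 0,
                                               effectSizeRange = c(0.1,
                                                                   0.15)))
  s1 <- assocScan(coh, "x1")
  s2 <- assocScan(coh, "x2")
  for (period in c("early", "late")) {
    st <- if (period == "early") list(s1, s2) else list(s2, s1)
    sets <- lapply(c("low", "low-medium", "medium-high", "high"),
                   function(t) selectInstruments(st[[1]], st[[2]], t,
                                                 targetPeriod = period))
    expect_true(all(sets[[2]]@snpIds %in% sets[[1]]@snpIds))
    expect_true(all(sets[[3]]@snpIds %in% sets[[2]]@snpIds))
    expect_true(all(sets[[4]]@snpIds %in% sets[[3]]@snpIds))
    # and counts weakly decrease
    expect_true(all(diff(vapply(sets, length, integer(1))) <= 0))
  }
})

test_that("stringent tiers recover the period-specific SNPs when tracking
           is absent", {
  # theta = 0 and no shared SNPs: the only route from an early SNP to x2 is
  # tracking, so removing it makes the periods genetically disjoint; large
  # effects ensure every true SNP clears genome-wide significance
  tr <- defaultSimulationTruth(seed = 32, nIndividuals = 50000, theta = 0,
                               nShared = 0L,
                               effectSizeRange = c(0.15, 0.2),
                               psi1 = 0, psi2 = 0)
  coh <- generateCohort(tr)
  s1 <- assocScan(coh, "x1")
  s2 <- assocScan(coh, "x2")
  earlyIds <- tr@snpIds[periodSpecificSnps(tr, "early")]
  # the Bonferroni tier recovers the early-specific set exactly
  mh <- selectInstruments(s1, s2, "medium-high", targetPeriod = "early")
  expect_setequal(mh@snpIds, earlyIds)
  # the P<=.05 tier is contamination-free but loses ~5% of true SNPs to
  # chance cross-period associations, so it is a subset
  high <- selectInstruments(s1, s2, "high", targetPeriod = "early")
  expect_true(all(high@snpIds %in% earlyIds))
  expect_gte(length(high), floor(0.8 * length(earlyIds)))
})

test_that("polygenic scores are weighted allele-count sums", {
  g <- matrix(c(0L, 2L, 1L, 0L), 2, 2, dimnames = list(NULL, c("a", "b")))
  ins <- new("InstrumentSet", snpIds = c("a", "b"), weights = c(0.5, 1.0),
             effectAllele = c("A", "A"), tier = "low",
             targetPeriod = "early")
  expect_equal(computePRS(g, ins), c(1.0, 1.0))

  zero <- new("InstrumentSet", snpIds = c("a", "b"), weights = c(0, 0),
              effectAllele = c("A", "A"), tier = "low",
              targetPeriod = "early")
  expect_equal(computePRS(g, zero), c(0, 0))

  single <- new("InstrumentSet", snpIds = "b", weights = 1,
                effectAllele = "A", tier = "low", targetPeriod = "early")
  expect_equal(computePRS(g, single), as.numeric(g[, "b"]))

  bad <- new("InstrumentSet", snpIds = "zz", weights = 1,
             effectAllele = "A", tier = "low", targetPeriod = "early")
  expect_error(computePRS(g, bad), "zz")
})

test_that("scores are linear in the weights", {
  g <- generateGenotypes(c(0.2, 0.3, 0.4), n = 40, seed = 5)
  mk <- function(w) new("InstrumentSet", snpIds = colnames(g), weights = w,
                        effectAllele = rep("A", 3), tier = "low",
                        targetPeriod = "early")
  w1 <- c(0.1, -0.2, 0.3); w2 <- c(0.05, 0.4, -0.1)
  expect_equal(computePRS(g, mk(w1 + w2)),
               computePRS(g, mk(w1)) + computePRS(g, mk(w2)),
               tolerance = 1e-12)
})

test_that("cohort and matrix PRS methods agree", {
  tr <- tinyTruth(seed = 33, n = 300)
  coh <- generateCohort(tr)
  s1 <- assocScan(coh, "x1")
  s2 <- assocScan(coh, "x2")
  # permissive threshold: any non-empty candidate set exercises the path
  ins <- selectInstruments(s1, s2, "low", gwThreshold = 0.5)
  expect_equal(computePRS(coh, ins), computePRS(genotypeMatrix(coh), ins))
})
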