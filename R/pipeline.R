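#' @include AllClasses.R AllGenerics.R cohort.R assocScan.R prs.R smm.R ivw.R
NULL

#' Construct an AnalysisConfig
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param tiers stringency tiers to run.
#' @param frameworks estimation frameworks to run.
#' @param sampleDesign \code{"one-sample"} (fully overlapping discovery and
#'   estimation, as when a single cohort supplies both) or
#'   \code{"split-sample"} (discovery scan on one random half, estimation on
#'   the other).
#' @param gwThreshold genome-wide significance threshold.
#' @param exposureCoding \code{"continuous"} (default) or \code{"tier"}
#'   (ordinal 1-3 coding of the thinner/average/plumper recoding).
#' @param nBoot bootstrap replicates (only used with bootstrap SEs).
#' @param seed seed for the split assignment and bootstraps.
#' @return a validated \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(truth,
                           tiers = c("low", "low-medium", "medium-high",
                                     "high"),
                           frameworks = c("smm-uni", "smm-multi", "ivw-uni",
                                          "ivw-mvmr"),
                           sampleDesign = c("one-sample", "split-sample"),
                           gwThreshold = 5e-8,
                           exposureCoding = c("continuous", "tier"),
                           nBoot = 1000L, seed = 1L) {
  sampleDesign <- match.arg(sampleDesign)
  exposureCoding <- match.arg(exposureCoding)
  new("AnalysisConfig", truth = truth, tiers = tiers,
      frameworks = frameworks, sampleDesign = sampleDesign,
      gwThreshold = gwThreshold, exposureCoding = exposureCoding,
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:", object@sampleDesign, "design,",
      object@truth@nIndividuals, "individuals\n")
  cat("  tiers:", paste(object@tiers, collapse = ", "), "\n")
  cat("  frameworks:", paste(object@frameworks, collapse = ", "), "\n")
  cat(sprintf("  gwThreshold %.3g; seed %d\n", object@gwThreshold,
              object@seed))
})

.resultRow <- function(exposure, estimator, tier, est, k, trueValue,
                       extra = list()) {
  rg <- if (is(est, "SmmEstimate")) est@regime@label
        else if (est@method == "ivw-mvmr") "controlled-period" else "period"
  data.frame(
    exposure = exposure, estimator = estimator, tier = tier,
    estimand_regime = rg,
    psi = if (is(est, "SmmEstimate")) est@psi[k] else est@beta[k],
    se = est@se[k], ci_low = est@ciLow[k], ci_high = est@ciHigh[k],
    n = if (is(est, "SmmEstimate")) est@nUsed else est@nSnps,
    first_stage_F = if (is(est, "SmmEstimate")) est@firstStageF[k]
                    else NA_real_,
    true_value = trueValue,
    stringsAsFactors = FALSE)
}

#' Run the full simulate-scan-select-score-estimate comparison
#'
#' Generates the cohort, scans both exposures (discovery sample) and the
#' outcome (estimation sample), selects instruments under each requested
#' tier for each period, builds polygenic scores, and estimates causal
#' effects under each requested framework.  Because the generating truth is
#' known, every row carries the target its estimator aims at: the total
#' early-period effect \code{psi1 + theta*psi2} for univariable early-period
#' analyses (early instruments also act on the outcome through tracking into
#' the late exposure), \code{psi2} for univariable late-period analyses, and
#' the controlled effects \code{(psi1, psi2)} for multivariable ones.
#' Tiers whose instrument selection comes up empty are reported and skipped;
#' the run continues.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param quiet suppress per-stage messages.
#' @return a list of class \code{"lifecourseRun"}: \code{results} (one row
#'   per exposure-tier-framework) and \code{report} (seed, clamp fraction,
#'   SNP counts per tier, empty tiers, per-stage timings, versions).
#' @examples
#' cfg <- analysisConfig(defaultSimulationTruth(seed = 9,
#'                                              nIndividuals = 4000),
#'                       tiers = "low", frameworks = "smm-uni")
#' run <- runAnalysis(cfg, quiet = TRUE)
#' run$results
#' @export
runAnalysis <- function(config, quiet = FALSE) {
  validObject(config)
  truth <- config@truth
  say <- function(...) if (!quiet) message(...)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  cohort <- generateCohort(truth)
  cohort <- filterCompleteCases(cohort, quiet = TRUE)
  timings["simulate"] <- tic() - t0
  say("simulated cohort: ", ncol(cohort), " individuals, ", nrow(cohort),
      " SNPs (clamped fraction ", signif(clampFraction(cohort), 3), ")")

  n <- ncol(cohort)
  if (config@sampleDesign == "split-sample") {
    half <- withSeed(config@seed, sample.int(n, n %/% 2L))
    disc <- cohort[, half]
    anal <- cohort[, -half]
  } else {
    disc <- cohort
    anal <- cohort
  }

  t0 <- tic()
  statsX1 <- assocScan(disc, "x1")
  statsX2 <- assocScan(disc, "x2")
  statsY <- assocScan(anal, "y")
  timings["scan"] <- tic() - t0
  say("association scans done (discovery n = ", ncol(disc),
      ", estimation n = ", ncol(anal), ")")

  cd <- colData(anal)
  xMat <- if (config@exposureCoding == "tier")
    cbind(early = as.numeric(cd$x1Tier), late = as.numeric(cd$x2Tier))
  else cbind(early = cd$x1, late = cd$x2)
  G <- genotypeMatrix(anal)
  # generating-truth targets are on the continuous exposure scale only
  uniTarget <- c(early = trueTotalEarlyEffect(truth), late = truth@psi2)
  ctrlTarget <- c(early = truth@psi1, late = truth@psi2)
  if (config@exposureCoding == "tier")
    uniTarget[] <- ctrlTarget[] <- NA_real_

  rows <- list()
  snpCounts <- list()
  emptyTiers <- character()
  t0 <- tic()
  for (tier in config@tiers) {
    instr <- list()
    for (period in .PERIODS) {
      st <- if (period == "early") list(statsX1, statsX2)
            else list(statsX2, statsX1)
      instr[[period]] <- tryCatch(
        selectInstruments(st[[1]], st[[2]], tier = tier,
                          gwThreshold = config@gwThreshold,
                          targetPeriod = period),
        error = function(e) {
          emptyTiers <<- c(emptyTiers, paste0(tier, "/", period))
          say("tier ", tier, ", ", period, "-period: ", conditionMessage(e))
          NULL
        })
    }
    snpCounts[[tier]] <- vapply(instr, function(i)
      if (is.null(i)) 0L else length(i), integer(1))
    prs <- lapply(instr, function(i)
      if (is.null(i)) NULL else computePRS(G, i))

    for (period in .PERIODS) {
      if (is.null(instr[[period]])) next
      if ("smm-uni" %in% config@frameworks) {
        est <- smmUnivariable(prs[[period]], xMat[, period], cd$y,
                              regime = "period", exposure = period)
        rows[[length(rows) + 1L]] <-
          .resultRow(period, "smm-uni", tier, est, 1L, uniTarget[[period]])
      }
      if ("ivw-uni" %in% config@frameworks) {
        st <- if (period == "early") statsX1 else statsX2
        sub <- st[match(instr[[period]]@snpIds, st$snp), , drop = FALSE]
        h <- suppressMessages(harmonize(sub, statsY))
        if (nrow(h) >= 2L) {
          est <- ivwUnivariable(h$bx_x, h$by, h$se_y, exposure = period)
          rows[[length(rows) + 1L]] <-
            .resultRow(period, "ivw-uni", tier, est, 1L, uniTarget[[period]])
        }
      }
    }
    if (!is.null(instr$early) && !is.null(instr$late)) {
      if ("smm-multi" %in% config@frameworks) {
        est <- smmMultivariable(cbind(early = prs$early, late = prs$late),
                                xMat, cd$y)
        for (k in 1:2)
          rows[[length(rows) + 1L]] <-
            .resultRow(.PERIODS[k], "smm-multi", tier, est, k,
                       ctrlTarget[[k]])
      }
      if ("ivw-mvmr" %in% config@frameworks) {
        ids <- union(instr$early@snpIds, instr$late@snpIds)
        sub1 <- statsX1[match(ids, statsX1$snp), , drop = FALSE]
        sub2 <- statsX2[match(ids, statsX2$snp), , drop = FALSE]
        h <- suppressMessages(
          harmonize(list(early = sub1, late = sub2), statsY))
        if (nrow(h) >= 3L) {
          est <- ivwMvmr(as.matrix(h[, c("bx_early", "bx_late")]), h$by,
                         h$se_y)
          est@exposures <- c("early", "late")
          for (k in 1:2)
            rows[[length(rows) + 1L]] <-
              .resultRow(.PERIODS[k], "ivw-mvmr", tier, est, k,
                         ctrlTarget[[k]])
        }
      }
    }
  }
  timings["estimate"] <- tic() - t0
  results <- if (length(rows)) do.call(rbind, rows) else
    .resultRow("early", "none", "none",
               new("SmmEstimate", psi = NA_real_, se = NA_real_,
                   ciLow = NA_real_, ciHigh = NA_real_, exposures = "early",
                   method = "smm-univariable", seMethod = "sandwich",
                   regime = estimandRegime("period"), nUsed = 0L,
                   firstStageF = NA_real_), 1L, NA_real_)[0, ]
  rownames(results) <- NULL
  out <- list(
    results = results,
    report = list(
      seed = config@seed, truthSeed = truth@seed,
      sampleDesign = config@sampleDesign,
      nIndividuals = n, nSnps = nrow(cohort),
      clampFraction = clampFraction(cohort),
      snpCountsPerTier = snpCounts,
      emptyTiers = emptyTiers,
      timings = timings,
      rVersion = R.version.string,
      packageVersion = as.character(packageVersion("lifecourseMR"))))
  class(out) <- "lifecourseRun"
  out
}

#' @export
print.lifecourseRun <- function(x, ...) {
  cat("lifecourseRun:", nrow(x$results), "estimates (",
      x$report$sampleDesign, "design, n =", x$report$nIndividuals, ")\n")
  df <- x$results
  df$psi <- signif(df$psi, 3)
  df$se <- signif(df$se, 3)
  df$ci_low <- signif(df$ci_low, 3)
  df$ci_high <- signif(df$ci_high, 3)
  df$first_stage_F <- signif(df$first_stage_F, 3)
  print(df, row.names = FALSE)
  if (length(x$report$emptyTiers))
    cat("empty tier selections:", paste(x$report$emptyTiers, collapse = ", "),
        "\n")
  invisible(x)
}

#' Monte-Carlo scenario: mediation of an early exposure through a late one
#'
#' Reproduces in silico the qualitative attenuation pattern seen when an
#' early-life exposure acts on a disease outcome mostly by tracking into the
#' later exposure: the univariable early-period estimate (oracle early-only
#' instruments) converges to the total effect \code{psi1 + theta*psi2},
#' while the controlled early-period estimate from the multivariable model
#' converges to the direct effect \code{psi1}.  Oracle period-specific
#' instruments (true effect weights on the SNPs acting on exactly one
#' period) isolate the structural phenomenon from instrument-selection
#' noise.  Requires \code{psi1 <= 0}, \code{psi2 > 0}, \code{theta >= 0}.
#'
#' @param config an \linkS4class{AnalysisConfig} (its truth defines the
#'   scenario; frameworks/tiers are ignored).
#' @param nReps number of replicate cohorts.
#' @param quiet suppress progress messages.
#' @return a list of class \code{"mediationReport"}: per-estimator means,
#'   Monte-Carlo standard errors, percentile intervals of the replicate
#'   means, the generating targets, and the sign-pattern flags.
#' @export
mediationScenario <- function(config, nReps = 200L, quiet = FALSE) {
  truth <- config@truth
  if (!(truth@psi1 <= 0 && truth@psi2 > 0 && truth@theta >= 0))
    stop("mediation scenario requires psi1 <= 0, psi2 > 0, theta >= 0",
         call. = FALSE)
  earlyIdx <- periodSpecificSnps(truth, "early")
  lateIdx <- periodSpecificSnps(truth, "late")
  if (!length(earlyIdx) || !length(lateIdx))
    stop("truth must contain period-specific SNPs for both periods",
         call. = FALSE)
  est <- matrix(NA_real_, nReps, 3L,
                dimnames = list(NULL, c("uniEarly", "ctrlEarly", "ctrlLate")))
  for (r in seq_len(nReps)) {
    tr <- truth
    tr@seed <- truth@seed + r
    coh <- suppressWarnings(generateCohort(tr))
    g <- genotypeMatrix(coh)
    cd <- colData(coh)
    zE <- drop(g[, earlyIdx, drop = FALSE] %*% truth@alpha1[earlyIdx])
    zL <- drop(g[, lateIdx, drop = FALSE] %*% truth@alpha2[lateIdx])
    uni <- smmUnivariable(zE, cd$x1, cd$y, exposure = "early")
    multi <- smmMultivariable(cbind(early = zE, late = zL),
                              cbind(early = cd$x1, late = cd$x2), cd$y)
    est[r, ] <- c(uni@psi, multi@psi)
    if (!quiet && r %% 50L == 0L) message("replicate ", r, "/", nReps)
  }
  mcMean <- colMeans(est)
  mcSe <- apply(est, 2L, sd) / sqrt(nReps)
  targets <- c(uniEarly = trueTotalEarlyEffect(truth),
               ctrlEarly = truth@psi1, ctrlLate = truth@psi2)
  out <- list(
    nReps = nReps, nIndividuals = truth@nIndividuals,
    mean = mcMean, mcSe = mcSe,
    ci = apply(est, 2L, quantile, probs = c(0.025, 0.975)),
    targets = targets,
    pattern = c(
      uniEarlyPositive = unname(mcMean["uniEarly"] - 3 * mcSe["uniEarly"]) > 0,
      ctrlEarlyCoversPsi1 = unname(
        abs(mcMean["ctrlEarly"] - truth@psi1) <= 3 * mcSe["ctrlEarly"]),
      ctrlLatePositive = unname(mcMean["ctrlLate"] - 3 * mcSe["ctrlLate"]) > 0),
    estimates = est)
  class(out) <- "mediationReport"
  out
}

#' @export
print.mediationReport <- function(x, ...) {
  cat("mediationReport:", x$nReps, "replicates at n =", x$nIndividuals, "\n")
  df <- data.frame(estimator = names(x$mean),
                   mean = signif(x$mean, 4),
                   mcSe = signif(x$mcSe, 3),
                   target = signif(x$targets, 4))
  print(df, row.names = FALSE)
  cat("sign pattern:",
      paste(names(x$pattern), x$pattern, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
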