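#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Simulate independent biallelic genotypes
#'
#' Each SNP is drawn independently under Hardy-Weinberg proportions: column
#' j holds n Binomial(2, maf_j) effect-allele counts.  No linkage
#' disequilibrium is simulated.
#'
#' @param maf vector of effect-allele frequencies in \[0,1\].
#' @param n number of individuals.
#' @param seed integer seed; the draw is deterministic given it.
#' @param snpIds optional column names.
#' @return an n-by-J integer matrix of allele counts.
#' @examples
#' g <- generateGenotypes(c(0.2, 0.5), n = 6, seed = 1)
#' @export
generateGenotypes <- function(maf, n, seed, snpIds = NULL) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 1))
    stop("maf entries must lie in [0,1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  J <- length(maf)
  g <- withSeed(seed, {
    matrix(rbinom(as.numeric(n) * J, 2L, rep(maf, each = n)), nrow = n)
  })
  storage.mode(g) <- "integer"
  colnames(g) <- if (is.null(snpIds)) sprintf("rs%05d", seq_len(J)) else snpIds
  g
}

#' Rank-based 3-tier recoding
#'
#' Mimics recall-questionnaire coding of a continuous measure: the lowest
#' \code{floor(n*p1)} ranked values become \code{"thinner"}, the next
#' \code{floor(n*(p1+p2)) - floor(n*p1)} become \code{"average"}, the rest
#' \code{"plumper"}.  Ties are broken by stable original order, so the split
#' is exact up to integer rounding even for degenerate inputs.
#'
#' @param values numeric vector without missing entries.
#' @param proportions 3-vector of tier proportions summing to 1.
#' @return an ordered factor with levels thinner < average < plumper.
#' @examples
#' table(categorizeThreeTier(1:10, c(0.3, 0.4, 0.3)))
#' @export
categorizeThreeTier <- function(values, proportions = c(1, 1, 1) / 3) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values to form 3 tiers", call. = FALSE)
  if (anyNA(values)) stop("values must have no missing entries", call. = FALSE)
  if (length(proportions) != 3L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must be a 3-vector summing to 1", call. = FALSE)
  n1 <- floor(n * proportions[1])
  n2 <- floor(n * (proportions[1] + proportions[2])) - n1
  ord <- order(values)                     # radix sort: stable for ties
  tier <- integer(n)
  tier[ord] <- rep.int(1:3, c(n1, n2, n - n1 - n2))
  factor(.TIER_LABELS[tier], levels = .TIER_LABELS, ordered = TRUE)
}

#' Assemble a LifecourseCohort from components
#'
#' Low-level constructor used by [generateCohort()] and [readCohort()];
#' genotypes are supplied individuals-by-SNPs and stored SNPs-by-individuals
#' in the \code{"genotypes"} assay.
#'
#' @param genotypes n-by-J integer matrix of effect-allele counts with SNP
#'   ids as column names.
#' @param x1,x2 continuous early / late exposures (length n).
#' @param y binary outcome (length n).
#' @param x1Tier,x2Tier optional 3-tier factors; computed from
#'   \code{tierProportions} when \code{NULL} and the exposure is complete.
#' @param covariates optional data.frame of covariate columns.
#' @param u optional latent confounder (simulated cohorts only).
#' @param truth optional \linkS4class{SimulationTruth}.
#' @param effectAllele,otherAllele optional per-SNP allele codes.
#' @param tierProportions proportions used when deriving missing tier columns.
#' @param clampFraction fraction of simulated risks that were clamped.
#' @return a \linkS4class{LifecourseCohort}.
#' @export
lifecourseCohort <- function(genotypes, x1, x2, y, x1Tier = NULL,
                             x2Tier = NULL, covariates = NULL, u = NULL,
                             truth = NULL, effectAllele = NULL,
                             otherAllele = NULL,
                             tierProportions = c(1, 1, 1) / 3,
                             clampFraction = NA_real_) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  deriveTier <- function(tier, x) {
    if (!is.null(tier))
      return(factor(as.character(tier), levels = .TIER_LABELS, ordered = TRUE))
    if (anyNA(x)) factor(rep(NA_character_, n), levels = .TIER_LABELS,
                         ordered = TRUE)
    else categorizeThreeTier(x, tierProportions)
  }
  cd <- DataFrame(x1 = as.numeric(x1), x2 = as.numeric(x2),
                  x1Tier = deriveTier(x1Tier, x1),
                  x2Tier = deriveTier(x2Tier, x2),
                  y = as.numeric(y))
  if (!is.null(u)) cd$u <- as.numeric(u)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in colnames(covariates)) cd[[nm]] <- covariates[[nm]]
  }
  rd <- DataFrame(
    snp = colnames(genotypes),
    effectAllele = if (is.null(effectAllele)) rep("A", ncol(genotypes))
                   else effectAllele,
    otherAllele = if (is.null(otherAllele)) rep("G", ncol(genotypes))
                  else otherAllele)
  se <- SummarizedExperiment(
    assays = list(genotypes = t(genotypes)),
    colData = cd, rowData = rd)
  rownames(se) <- colnames(genotypes)
  obj <- new("LifecourseCohort", se)
  metadata(obj)$clampFraction <- clampFraction
  if (!is.null(truth)) metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' Generate a synthetic two-period cohort
#'
#' Draws genotypes under Hardy-Weinberg, a standard-normal latent confounder
#' U, exposures
#' \deqn{X_1 = G\alpha_1 + c_1 U + N(0, \sigma_1^2),\quad
#'       X_2 = \theta X_1 + G\alpha_2 + c_2 U + N(0, \sigma_2^2),}
#' and a binary outcome from the linear-probability model
#' \eqn{p = b_0 + \psi_1 X_1 + \psi_2 X_2 + c_y U} clamped to
#' \code{[eps, 1-eps]}.  The clamped fraction is recorded in the cohort
#' metadata; clamping degrades the risk-difference identification, so a
#' fraction above \code{clampCeiling} raises a warning (an error when
#' \code{strict = TRUE}).  Both 3-tier recodings use the same tier
#' proportions, mirroring how a recall-style categorical measure is matched
#' by recoding a continuous one.  The whole cohort is a deterministic
#' function of the truth object (including its seed).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param eps clamp bound for the risk (default 1e-6).
#' @param clampCeiling maximum tolerated clamped fraction (default 0.01).
#' @param strict escalate the clamp warning to an error.
#' @return a \linkS4class{LifecourseCohort} carrying \code{truth}, the latent
#'   confounder column \code{u} and the clamped fraction in its metadata.
#' @examples
#' coh <- generateCohort(defaultSimulationTruth(seed = 3, nIndividuals = 500))
#' clampFraction(coh)
#' @export
generateCohort <- function(truth, eps = 1e-6, clampCeiling = 0.01,
                           strict = FALSE) {
  validObject(truth)
  n <- truth@nIndividuals
  sim <- withSeed(truth@seed, {
    J <- length(truth@maf)
    g <- matrix(rbinom(as.numeric(n) * J, 2L, rep(truth@maf, each = n)),
                nrow = n)
    u <- rnorm(n)
    # genetic contributions as deviations from the population genotype mean
    # (2f per SNP), so baselineRisk is the mean risk whatever the realized
    # effect signs
    x1 <- drop(g %*% truth@alpha1) - sum(2 * truth@maf * truth@alpha1) +
      truth@confLoadX1 * u + rnorm(n, 0, truth@sigma1)
    x2 <- truth@theta * x1 + drop(g %*% truth@alpha2) -
      sum(2 * truth@maf * truth@alpha2) +
      truth@confLoadX2 * u + rnorm(n, 0, truth@sigma2)
    p <- truth@baselineRisk + truth@psi1 * x1 + truth@psi2 * x2 +
      truth@confLoadY * u
    clamped <- mean(p < eps | p > 1 - eps)
    p <- pmin(pmax(p, eps), 1 - eps)
    y <- rbinom(n, 1L, p)
    list(g = g, u = u, x1 = x1, x2 = x2, y = y, clamped = clamped)
  })
  if (sim$clamped > clampCeiling) {
    msg <- sprintf(paste("%.2f%% of simulated risks were clamped to [eps,",
                         "1-eps]; the linear-probability identification is",
                         "degraded (ceiling %.2f%%)"),
                   100 * sim$clamped, 100 * clampCeiling)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  storage.mode(sim$g) <- "integer"
  colnames(sim$g) <- truth@snpIds
  lifecourseCohort(sim$g, x1 = sim$x1, x2 = sim$x2, y = sim$y,
                   u = sim$u, truth = truth,
                   effectAllele = truth@effectAllele,
                   otherAllele = truth@otherAllele,
                   tierProportions = truth@tierProportions,
                   clampFraction = sim$clamped)
}

#' Drop individuals with incomplete exposure or outcome data
#'
#' Keeps rows with both exposures and the outcome observed, the complete-case
#' rule applied before any estimation; the retained count is reported.
#'
#' @param cohort a \linkS4class{LifecourseCohort}.
#' @param quiet suppress the retained-count message.
#' @return the filtered \linkS4class{LifecourseCohort}.
#' @export
filterCompleteCases <- function(cohort, quiet = FALSE) {
  cd <- colData(cohort)
  keep <- !is.na(cd$x1) & !is.na(cd$x2) & !is.na(cd$y)
  if (!any(keep))
    stop("no individuals with complete exposure and outcome data",
         call. = FALSE)
  if (!quiet)
    message(sum(keep), " of ", length(keep),
            " individuals retained with complete exposures and outcome")
  cohort[, keep]
}

#' @describeIn cohortAccessors individuals-by-SNPs matrix of effect-allele
#'   counts (the transpose of the stored assay).
#' @export
setMethod("genotypeMatrix", "LifecourseCohort", function(object)
  t(assay(object, "genotypes")))

#' @describeIn cohortAccessors the \linkS4class{SimulationTruth} carried by a
#'   simulated cohort, or NULL.
#' @export
setMethod("simTruth", "LifecourseCohort", function(object)
  metadata(object)$truth)

#' @describeIn cohortAccessors fraction of simulated risks clamped into
#'   \code{[eps, 1-eps]}.
#' @export
setMethod("clampFraction", "LifecourseCohort", function(object)
  metadata(object)$clampFraction)

#' Accessors for LifecourseCohort
#'
#' @param object a \linkS4class{LifecourseCohort}.
#' @name cohortAccessors
#' @describeIn cohortAccessors the observed-data view: latent confounder and
#'   generating truth removed, as an analyst of real data would see it.
#' @export
setMethod("observedCohort", "LifecourseCohort", function(object) {
  colData(object)$u <- NULL
  metadata(object)$truth <- NULL
  object
})

setMethod("show", "LifecourseCohort", function(object) {
  cat("LifecourseCohort:", ncol(object), "individuals,", nrow(object),
      "SNPs\n")
  cd <- colData(object)
  cat(sprintf("  outcome prevalence %.3f; missing x1/x2/y: %d/%d/%d\n",
              mean(cd$y, na.rm = TRUE), sum(is.na(cd$x1)),
              sum(is.na(cd$x2)), sum(is.na(cd$y))))
  extra <- setdiff(colnames(cd), c("x1", "x2", "x1Tier", "x2Tier", "y"))
  if (length(extra))
    cat("  additional columns:", paste(extra, collapse = ", "), "\n")
  cf <- clampFraction(object)
  if (!is.null(cf) && !is.na(cf))
    cat(sprintf("  simulated: clamped-risk fraction %.4g%s\n", cf,
                if (is.null(simTruth(object))) "" else "; truth attached"))
})
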