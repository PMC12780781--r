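#' @include AllClasses.R utils.R
NULL

#' Per-SNP association scan
#'
#' Ordinary least squares of a trait on each SNP's effect-allele count, with
#' optional covariate adjustment (via Frisch-Waugh residualization, which is
#' exactly the multiple regression fit).  Binary traits are analyzed on the
#' linear-probability scale, so SNP-outcome effects are risk differences and
#' share units with the structural-mean-model estimands.  P-values use the
#' two-sided normal approximation on beta/se, the usual convention for GWAS
#' summary statistics; the residual variance keeps its n - C - 2 degrees of
#' freedom.  SNPs with no genotype variance after covariate adjustment are
#' flagged \code{monomorphic} with NA estimates and are excluded from
#' instrument candidacy downstream.
#'
#' @param cohort a \linkS4class{LifecourseCohort}.
#' @param trait name of a \code{colData} column (\code{"x1"}, \code{"x2"},
#'   \code{"y"}, ...).
#' @param covariates character vector of \code{colData} covariate column
#'   names, or NULL.
#' @return a \code{SummaryStats} data.frame with columns \code{snp},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#'   \code{pval}, \code{n} and a logical \code{monomorphic} flag.
#' @examples
#' coh <- generateCohort(defaultSimulationTruth(seed = 2, nIndividuals = 800))
#' head(assocScan(coh, "x1"))
#' @export
assocScan <- function(cohort, trait, covariates = NULL) {
  cd <- colData(cohort)
  if (!trait %in% colnames(cd))
    stop("trait column '", trait, "' not found in colData", call. = FALSE)
  if (length(covariates)) {
    miss <- setdiff(covariates, colnames(cd))
    if (length(miss))
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  yv <- cd[[trait]]
  keep <- !is.na(yv)
  covMat <- if (length(covariates))
    as.matrix(as.data.frame(cd[covariates])) else NULL
  if (!is.null(covMat)) keep <- keep & stats::complete.cases(covMat)
  G <- genotypeMatrix(cohort)[keep, , drop = FALSE]
  yv <- as.numeric(yv[keep])
  covMat <- if (is.null(covMat)) NULL else covMat[keep, , drop = FALSE]
  n <- length(yv)
  nC <- if (is.null(covMat)) 0L else ncol(covMat)
  if (n <= nC + 2L)
    stop("need more individuals than covariates + 2", call. = FALSE)

  ey <- drop(residualizeOn(yv, covMat))
  EG <- residualizeOn(G, covMat)
  sxx <- colSums(EG^2)
  sxy <- drop(crossprod(EG, ey))
  syy <- sum(ey^2)
  mono <- sxx <= n * 1e-12
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  df <- n - nC - 2L
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / df / sxx))
  z <- beta / se
  pval <- 2 * pnorm(-abs(z))
  rd <- rowData(cohort)
  out <- data.frame(
    snp = as.character(rd$snp),
    effect_allele = as.character(rd$effectAllele),
    other_allele = as.character(rd$otherAllele),
    beta = beta, se = se, pval = pval, n = n,
    monomorphic = mono,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("SummaryStats", "data.frame")
  out
}

#' Read and write GWAS summary statistics
#'
#' Tab-separated dialect with columns \code{snp}, \code{effect_allele},
#' \code{other_allele}, \code{beta}, \code{se}, \code{pval}, \code{n}
#' (dot decimal, scientific notation accepted).  Monomorphic records are
#' dropped on write with a message.
#'
#' @param stats a SummaryStats data.frame.
#' @param path file path.
#' @return \code{readSummaryStats} returns a SummaryStats data.frame;
#'   \code{writeSummaryStats} returns \code{path} invisibly.
#' @export
writeSummaryStats <- function(stats, path) {
  if (!is.null(stats$monomorphic) && any(stats$monomorphic)) {
    message("dropping ", sum(stats$monomorphic),
            " monomorphic record(s) on write")
    stats <- stats[!stats$monomorphic, , drop = FALSE]
  }
  cols <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  miss <- setdiff(cols, colnames(stats))
  if (length(miss))
    stop("missing summary-statistics column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  write.table(stats[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  cols <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  miss <- setdiff(cols, colnames(out))
  if (length(miss))
    stop("missing summary-statistics column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in c("beta", "se", "pval")) out[[nm]] <- as.numeric(out[[nm]])
  out$n <- as.integer(out$n)
  out$monomorphic <- FALSE
  class(out) <- c("SummaryStats", "data.frame")
  out
}
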