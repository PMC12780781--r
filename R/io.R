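#' @include AllClasses.R cohort.R
NULL

.PHENO_COLS <- c("x1", "x2", "x1_tier", "x2_tier", "y")

#' Write and read cohorts as tab-separated text
#'
#' The on-disk dialect follows the PLINK \code{.raw} convention for
#' genotypes: one column per SNP named \code{<snp>_<effect allele>} holding
#' effect-allele counts, preceded by \code{FID}/\code{IID} and followed by
#' the phenotype columns \code{x1}, \code{x2}, \code{x1_tier},
#' \code{x2_tier}, \code{y} and any covariates.  Missing values are
#' \code{NA}.  The latent confounder and generating truth are never written:
#' the file is the observed-data view.  Use [writeTruth()] for the sidecar.
#'
#' @param cohort a \linkS4class{LifecourseCohort}.
#' @param path file path.
#' @return \code{readCohort} returns a \linkS4class{LifecourseCohort};
#'   \code{writeCohort} returns \code{path} invisibly.
#' @export
writeCohort <- function(cohort, path) {
  obs <- observedCohort(cohort)
  g <- genotypeMatrix(obs)
  rd <- rowData(obs)
  colnames(g) <- paste0(rd$snp, "_", rd$effectAllele)
  cd <- as.data.frame(colData(obs))
  out <- data.frame(FID = seq_len(nrow(g)), IID = seq_len(nrow(g)))
  out <- cbind(out, as.data.frame(g),
               data.frame(x1 = cd$x1, x2 = cd$x2,
                          x1_tier = as.character(cd$x1Tier),
                          x2_tier = as.character(cd$x2Tier),
                          y = cd$y))
  extra <- setdiff(colnames(cd), c("x1", "x2", "x1Tier", "x2Tier", "y"))
  for (nm in extra) out[[nm]] <- cd[[nm]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @param truth optional \linkS4class{SimulationTruth} (e.g. from
#'   [readTruth()]) to re-attach to the cohort.
#' @export
readCohort <- function(path, truth = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("FID", "IID", .PHENO_COLS)
  gCols <- grep("_[A-Z]+$", setdiff(colnames(tab), fixed), value = TRUE)
  if (!length(gCols))
    stop("no genotype columns (named <snp>_<allele>) found", call. = FALSE)
  g <- as.matrix(tab[gCols])
  storage.mode(g) <- "integer"
  snp <- sub("_[A-Z]+$", "", gCols)
  allele <- sub("^.*_", "", gCols)
  colnames(g) <- snp
  covCols <- setdiff(colnames(tab), c(fixed, gCols))
  lifecourseCohort(
    g, x1 = tab$x1, x2 = tab$x2, y = tab$y,
    x1Tier = if ("x1_tier" %in% colnames(tab)) tab$x1_tier,
    x2Tier = if ("x2_tier" %in% colnames(tab)) tab$x2_tier,
    covariates = if (length(covCols)) tab[covCols],
    truth = truth, effectAllele = allele)
}

#' Write a results table of causal estimates
#'
#' Tab-separated with columns \code{exposure}, \code{estimator}, \code{tier},
#' \code{estimand_regime}, \code{psi}, \code{se}, \code{ci_low},
#' \code{ci_high}, \code{n}, \code{first_stage_F} (plus any extra columns
#' present) — the machine-readable twin of a forest plot.
#'
#' @param results the results data.frame of [runAnalysis()].
#' @param path file path.
#' @export
writeEstimates <- function(results, path) {
  need <- c("exposure", "estimator", "tier", "estimand_regime", "psi", "se",
            "ci_low", "ci_high", "n", "first_stage_F")
  miss <- setdiff(need, colnames(results))
  if (length(miss))
    stop("missing results column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write an AnalysisConfig as YAML
#'
#' The truth parameters are nested under \code{truth}; remaining fields
#' mirror the \linkS4class{AnalysisConfig} slots.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param path file path.
#' @export
writeAnalysisConfig <- function(config, path) {
  tr <- config@truth
  x <- list(
    truth = {
      sl <- slotNames(tr)
      v <- lapply(sl, function(s) slot(tr, s)); names(v) <- sl; v
    },
    tiers = config@tiers, frameworks = config@frameworks,
    sampleDesign = config@sampleDesign, gwThreshold = config@gwThreshold,
    exposureCoding = config@exposureCoding,
    nBoot = config@nBoot, seed = config@seed)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  x <- yaml::read_yaml(path)
  analysisConfig(truth = do.call(simulationTruth, x$truth),
                 tiers = x$tiers, frameworks = x$frameworks,
                 sampleDesign = x$sampleDesign,
                 gwThreshold = x$gwThreshold,
                 exposureCoding = if (is.null(x$exposureCoding))
                   "continuous" else x$exposureCoding,
                 nBoot = x$nBoot, seed = x$seed)
}
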