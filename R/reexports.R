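# Re-exports so cohort objects are usable without attaching the
# SummarizedExperiment stack explicitly.

#' @importFrom SummarizedExperiment assay colData rowData assayNames
#' @export
SummarizedExperiment::assay

#' @export
SummarizedExperiment::colData

#' @export
SummarizedExperiment::rowData

#' @export
SummarizedExperiment::assayNames

#' @importMethodsFrom SummarizedExperiment "colData<-"
#' @export
SummarizedExperiment::`colData<-`

#' @export
S4Vectors::metadata
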