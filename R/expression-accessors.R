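# Accessors for RelExpressionSet beyond what SummarizedExperiment provides.

#' Mean normalized relative quantity
#'
#' @param x A [RelExpressionSet-class].
#' @return Numeric genes-by-conditions matrix.
#' @export
meanQ <- function(x) SummarizedExperiment::assay(x, "meanQ")

#' Replicate standard deviation of the normalized quantity
#'
#' @param x A [RelExpressionSet-class].
#' @return Numeric genes-by-conditions matrix.
#' @export
sdQ <- function(x) SummarizedExperiment::assay(x, "sdQ")

#' Condition type of each column
#'
#' @param x A [RelExpressionSet-class].
#' @return Character vector, \code{"stage"} or \code{"organ"} per column.
#' @export
conditionType <- function(x) SummarizedExperiment::colData(x)$conditionType

#' Numeric stage value of each column
#'
#' @param x A [RelExpressionSet-class].
#' @return Numeric vector (\code{NA} for organ columns).
#' @export
stageValues <- function(x) SummarizedExperiment::colData(x)$stageValue

#' Subset to the developmental time course
#'
#' Returns the stage columns, ordered by increasing stage value.
#'
#' @param x A [RelExpressionSet-class].
#' @return A [RelExpressionSet-class] with stage columns only.
#' @export
timeCourse <- function(x) {
    keep <- which(conditionType(x) == "stage")
    x[, keep[order(stageValues(x)[keep])]]
}

#' Subset to the floral-organ panel
#'
#' @param x A [RelExpressionSet-class].
#' @return A [RelExpressionSet-class] with organ columns only, in canonical
#'   whorl order where the canonical organs are present.
#' @export
organPanel <- function(x) {
    keep <- which(conditionType(x) == "organ")
    nm <- colnames(x)[keep]
    canon <- intersect(floralOrgans(), nm)
    x[, keep[order(match(nm, canon))]]
}
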