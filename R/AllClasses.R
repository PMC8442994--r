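#' @import methods
#' @importFrom stats contr.helmert cor cutree dist hclust plogis quantile rnorm sd setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Floral organs scored by the conformance reporter
#'
#' The five floral organs of the barley floret, ordered from the outermost
#' whorl inwards.  Lemma and palea are both whorl-1 organs, the lodicule is
#' the grass petal homolog (whorl 2), stamens are whorl 3 and the carpel is
#' whorl 4.
#'
#' @return Character vector of the five organ names.
#' @export
#' @examples
#' floralOrgans()
floralOrgans <- function() c("lemma", "palea", "lodicule", "stamen", "carpel")

#' StageGrid: ordered developmental stages with numeric stage values
#'
#' A Waddington-style staging grid: ordered stage labels paired with strictly
#' increasing numeric stage values.  The default grid holds the 11 stages
#' commonly sampled through cereal inflorescence development, from the floral
#' transition (W1) to three days past pollination (W10.5).
#'
#' @slot labels Ordered character vector of stage identifiers.
#' @slot values Matching numeric stage values (dimensionless), strictly
#'   increasing.
#'
#' @aliases StageGrid-class
#' @export StageGrid
#' @exportClass StageGrid
StageGrid <- setClass("StageGrid",
    representation(labels = "character", values = "numeric"))

setValidity("StageGrid", function(object) {
    if (length(object@labels) != length(object@values))
        return("labels and values must have equal length")
    if (length(object@values) < 2L)
        return("a stage grid needs at least two stages")
    if (any(diff(object@values) <= 0))
        return("stage values must be strictly increasing")
    if (anyDuplicated(object@labels))
        return("stage labels must be unique")
    TRUE
})

#' Default developmental stage grid (W1 to W10.5)
#'
#' The 11 sampled Waddington stages: W1, W1.5, W2, W2.5, W3.5, W4, W4.5,
#' W6.5, W8.5, W9.5 and W10.5 (the last taken 3 days after pollination).
#'
#' @return A [StageGrid] object.
#' @export
#' @examples
#' defaultStageGrid()
defaultStageGrid <- function() {
    v <- c(1, 1.5, 2, 2.5, 3.5, 4, 4.5, 6.5, 8.5, 9.5, 10.5)
    StageGrid(labels = paste0("W", v), values = v)
}

setMethod("show", "StageGrid", function(object) {
    cat("StageGrid with", length(object@labels), "stages:",
        paste(object@labels, collapse = " "), "\n")
})

#' CqTable: raw quantification-cycle measurements
#'
#' Long-format container for raw RT-qPCR quantification cycles: one record
#' per (gene, condition, technical replicate).  Conditions are either
#' developmental stages or floral organs; a missing Cq (\code{NA}) records a
#' reaction with no amplification.
#'
#' @slot records A data.frame with columns \code{gene}, \code{conditionType}
#'   (\code{"stage"} or \code{"organ"}), \code{condition}, \code{replicate}
#'   and \code{cq} (cycles; \code{NA} = no amplification).
#'
#' @seealso [readCqTable()], [writeCqTable()], [normalizeCq()]
#' @aliases CqTable-class
#' @export CqTable
#' @exportClass CqTable
CqTable <- setClass("CqTable", representation(records = "data.frame"))

setValidity("CqTable", function(object) {
    r <- object@records
    need <- c("gene", "conditionType", "condition", "replicate", "cq")
    if (!all(need %in% names(r)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (!all(r$conditionType %in% c("stage", "organ")))
        return("conditionType must be 'stage' or 'organ'")
    if (any(!is.na(r$cq) & (!is.finite(r$cq) | r$cq <= 0)))
        return("cq values must be finite and > 0 when present")
    if (any(is.na(r$replicate) | r$replicate < 1))
        return("replicate indices must be positive integers")
    TRUE
})

#' @describeIn CqTable Access the measurement records.
#' @param x A \code{CqTable}.
#' @export
cqRecords <- function(x) {
    stopifnot(is(x, "CqTable"))
    x@records
}

setMethod("show", "CqTable", function(object) {
    r <- object@records
    cat("CqTable:", length(unique(r$gene)), "assays,",
        length(unique(r$condition[r$conditionType == "stage"])), "stages,",
        length(unique(r$condition[r$conditionType == "organ"])), "organs,",
        nrow(r), "records\n")
    cat("  missing Cq (no amplification):", sum(is.na(r$cq)), "\n")
})

#' RelExpressionSet: normalized relative expression with replicate spread
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' output of delta-Cq normalization: per gene and condition the mean
#' normalized relative quantity over technical replicates (assay
#' \code{meanQ}) and the replicate standard deviation (assay \code{sdQ}).
#' Column metadata records whether each condition is a developmental stage
#' or a floral organ, and the numeric stage value where applicable.
#'
#' @aliases RelExpressionSet-class
#' @export
#' @exportClass RelExpressionSet
setClass("RelExpressionSet", contains = "SummarizedExperiment")

setValidity("RelExpressionSet", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("meanQ", "sdQ") %in% a))
        return("assays 'meanQ' and 'sdQ' are required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("conditionType", "stageValue") %in% names(cd)))
        return("colData must have 'conditionType' and 'stageValue'")
    if (!all(cd$conditionType %in% c("stage", "organ")))
        return("conditionType must be 'stage' or 'organ'")
    m <- SummarizedExperiment::assay(object, "meanQ")
    s <- SummarizedExperiment::assay(object, "sdQ")
    if (any(m < 0, na.rm = TRUE) || any(s < 0, na.rm = TRUE))
        return("meanQ and sdQ must be nonnegative")
    TRUE
})

#' Construct a RelExpressionSet
#'
#' @param meanQ,sdQ Numeric gene-by-condition matrices with identical
#'   dimnames: mean and standard deviation of the normalized relative
#'   quantity over technical replicates.
#' @param conditionType Character vector, one of \code{"stage"}/\code{"organ"}
#'   per column.
#' @param stageValue Numeric stage value per column (\code{NA} for organs).
#'
#' @return A \code{RelExpressionSet}.
#' @export
RelExpressionSet <- function(meanQ, sdQ, conditionType, stageValue = NA_real_) {
    stopifnot(identical(dim(meanQ), dim(sdQ)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meanQ = meanQ, sdQ = sdQ),
        colData = S4Vectors::DataFrame(
            conditionType = rep(conditionType, length.out = ncol(meanQ)),
            stageValue = rep(stageValue, length.out = ncol(meanQ)),
            row.names = colnames(meanQ)))
    methods::new("RelExpressionSet", se)
}

setMethod("show", "RelExpressionSet", function(object) {
    ct <- SummarizedExperiment::colData(object)$conditionType
    cat("RelExpressionSet:", nrow(object), "genes x", ncol(object),
        "conditions (", sum(ct == "stage"), "stages,",
        sum(ct == "organ"), "organs )\n")
})

#' GroundTruth: generator group labels and noise-free profiles
#'
#' Emitted alongside every synthetic dataset: the true group of each gene
#' (\code{set1}, \code{set2}, \code{set3}, \code{pseudoset},
#' \code{ungrouped} or \code{reference}), its noise-free expression profile
#' over the stage grid, and its noise-free organ profile.
#'
#' @slot groupOf Named character vector: gene to true group label.
#' @slot profiles Numeric matrix (genes x stages) of noise-free expression.
#' @slot organProfiles Numeric matrix (genes x organs); reference genes
#'   carry flat rows.
#' @slot stageGrid The [StageGrid] the profiles are evaluated on.
#'
#' @aliases GroundTruth-class
#' @export
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(groupOf = "character", profiles = "matrix",
                   organProfiles = "matrix", stageGrid = "StageGrid"))

setValidity("GroundTruth", function(object) {
    ok <- c("set1", "set2", "set3", "pseudoset", "ungrouped", "reference")
    if (!all(object@groupOf %in% ok))
        return(paste("unknown group label; allowed:", paste(ok, collapse = ", ")))
    if (anyDuplicated(names(object@groupOf)))
        return("each gene must appear exactly once")
    if (!setequal(names(object@groupOf), rownames(object@profiles)))
        return("profiles rows must match groupOf genes")
    if (any(object@profiles < 0) || any(object@organProfiles < 0))
        return("true profiles must be nonnegative")
    TRUE
})

#' @describeIn GroundTruth Named character vector of true group labels.
#' @param x A \code{GroundTruth}.
#' @export
groupOf <- function(x) {
    stopifnot(is(x, "GroundTruth"))
    x@groupOf
}

#' @describeIn GroundTruth Noise-free stage profiles (genes x stages).
#' @export
trueProfiles <- function(x) {
    stopifnot(is(x, "GroundTruth"))
    x@profiles
}

#' @describeIn GroundTruth Noise-free organ profiles (genes x organs).
#' @export
trueOrganProfiles <- function(x) {
    stopifnot(is(x, "GroundTruth"))
    x@organProfiles
}

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@groupOf), "genes\n")
    print(table(object@groupOf))
})

#' SetAssignment: partition of genes into correlation sets
#'
#' The result of the threshold-graph set rule: genes partitioned into
#' ordered correlation sets (\code{set_1}, \code{set_2}, ...; earliest mean
#' peak stage first), at most one \code{pseudoset}, and \code{ungrouped}
#' genes.  For set members, \code{nPartners} records the number of
#' within-set partners with r above the primary threshold.
#'
#' @slot labels Named character vector: gene to label.
#' @slot nPartners Named integer vector: within-set qualifying partners
#'   (0 for pseudoset/ungrouped genes).
#' @slot peakStage Named character vector: stage of maximum mean expression.
#' @slot params The [setRuleParams()] used.
#'
#' @aliases SetAssignment-class
#' @export
#' @exportClass SetAssignment
setClass("SetAssignment",
    representation(labels = "character", nPartners = "integer",
                   peakStage = "character", params = "list"))

setValidity("SetAssignment", function(object) {
    if (!identical(names(object@labels), names(object@nPartners)))
        return("labels and nPartners must cover the same genes")
    TRUE
})

#' @describeIn SetAssignment Named character vector of labels.
#' @param x A \code{SetAssignment}.
#' @export
setLabels <- function(x) {
    stopifnot(is(x, "SetAssignment"))
    x@labels
}

#' @describeIn SetAssignment Genes carrying a given label.
#' @param label A label such as \code{"set_1"} or \code{"pseudoset"}.
#' @export
setMembers <- function(x, label) {
    stopifnot(is(x, "SetAssignment"))
    names(x@labels)[x@labels == label]
}

setMethod("show", "SetAssignment", function(object) {
    cat("SetAssignment:", length(object@labels), "genes\n")
    print(table(object@labels))
})
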