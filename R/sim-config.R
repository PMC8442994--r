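#' SimConfig: parameters of the synthetic RT-qPCR generator
#'
#' Describes the simulated study: the gene roster (group sizes, ABCDE class
#' labels), the temporal template of each co-expression group, the reference
#' panel and its per-candidate Cq noise, technical-replicate noise, the
#' antisense-overlap assay pair and the missing-Cq floor.  Defaults emulate
#' a barley MIKCc MADS-box profiling study: ~30 assays over 11 Waddington
#' stages and 5 floral organs with 3 technical replicates, a 4-candidate
#' reference panel with one destabilized member, three tight co-expression
#' blocks, a looser early pseudoset, and independent erratic genes.
#'
#' @slot genes data.frame with columns \code{gene}, \code{group},
#'   \code{class} (ABCDE class or \code{"other"}) and \code{baseScale}.
#' @slot stageGrid The [StageGrid] sampled by the time course.
#' @slot organs Floral organ labels (5).
#' @slot groupParams Per-group temporal template parameters; see
#'   [simConfig()].
#' @slot referencePanel data.frame(\code{gene}, \code{conditionSd}):
#'   4 candidates with per-candidate between-condition Cq noise (cycles).
#' @slot replicateSd Technical-replicate Cq noise, cycles.
#' @slot biologicalJitterSd Per-gene multiplicative template perturbation
#'   (sd of log expression) for set members.
#' @slot pseudoJitterSd Jitter for pseudoset members (larger).
#' @slot scaleSd Spread of the per-gene lognormal scale factor.
#' @slot baseCq Cq anchoring relative expression 1.0 (cycles).
#' @slot overlapPair Named character vector \code{c(target=, background=)}
#'   for the antisense-overlap assay pair, or empty for none.
#' @slot resurgenceEnabled If TRUE, the first set1 gene gains a second
#'   expression peak late in development (a known grouping stressor;
#'   default off).
#' @slot expressionFloor Fraction of a gene's maximum below which a
#'   measurement is emitted as missing Cq (no amplification).
#' @slot organNoiseSd Multiplicative lognormal noise on organ weights.
#' @slot organDeviations data.frame(\code{gene}, \code{organ},
#'   \code{weight}) of injected off-model organ expression.
#' @slot nReplicates Technical replicates per reaction.
#'
#' @aliases SimConfig-class
#' @export
#' @exportClass SimConfig
setClass("SimConfig",
    representation(genes = "data.frame", stageGrid = "StageGrid",
                   organs = "character", groupParams = "list",
                   referencePanel = "data.frame", replicateSd = "numeric",
                   biologicalJitterSd = "numeric", pseudoJitterSd = "numeric",
                   scaleSd = "numeric", baseCq = "numeric",
                   overlapPair = "character", resurgenceEnabled = "logical",
                   expressionFloor = "numeric", organNoiseSd = "numeric",
                   organDeviations = "data.frame", nReplicates = "integer"))

setValidity("SimConfig", function(object) {
    okGroups <- c("set1", "set2", "set3", "pseudoset", "ungrouped")
    if (!all(object@genes$group %in% okGroups))
        return(paste("invalid group name; allowed:",
                     paste(okGroups, collapse = ", ")))
    if (anyDuplicated(c(object@genes$gene, object@referencePanel$gene)))
        return("gene names must be unique across targets and references")
    if (nrow(object@referencePanel) != 4L)
        return("exactly 4 reference candidates are required")
    sds <- c(object@replicateSd, object@biologicalJitterSd,
             object@pseudoJitterSd, object@scaleSd, object@organNoiseSd,
             object@referencePanel$conditionSd)
    if (any(sds < 0)) return("noise standard deviations must be >= 0")
    if (length(object@organs) != 5L) return("exactly 5 organs are required")
    if (length(object@overlapPair) &&
        (!all(c("target", "background") %in% names(object@overlapPair)) ||
         !all(object@overlapPair %in% object@genes$gene)))
        return("overlapPair must name a target and a background gene from the roster")
    if (object@expressionFloor < 0 || object@expressionFloor >= 1)
        return("expressionFloor must be in [0, 1)")
    TRUE
})

# Default gene roster.  Group sizes follow the emulated study: a trio of
# SVP-like floral repressors (set1), six floral-organ builders peaking just
# before pollination (set2), seven carpel/ovule genes peaking after
# pollination (set3), six loosely co-expressed early genes (pseudoset) and
# three erratic low-abundance genes plus the antisense kinase assay
# (ungrouped).  Class labels drive the organ-profile expectations.
defaultGeneRoster <- function() {
    df <- function(...) data.frame(..., stringsAsFactors = FALSE)
    rbind(
        df(gene = c("SVP1", "SVP2", "SVP3"), group = "set1",
           class = "other", baseScale = 2.0),
        df(gene = c("AP1", "PI1", "PI2", "AP3", "AG1", "SEP1"),
           group = "set2",
           class = c("A", "B", "B", "B", "C", "E-LOFSEP"), baseScale = 1.5),
        df(gene = c("AG2", "D1", "D2", "SEP3a", "SEP3b", "BS1", "BS2"),
           group = "set3",
           class = c("C", "D", "D", "E-SEP3", "E-SEP3", "other", "other"),
           baseScale = 1.0),
        df(gene = c("AP1e1", "AP1e2", "LSEP1", "LSEP2", "SOC1a", "SOC1b"),
           group = "pseudoset",
           class = c("A", "A", "E-LOFSEP", "E-LOFSEP", "other", "other"),
           baseScale = 1.0),
        df(gene = c("AGL17a", "AGL17b", "AGL17c"), group = "ungrouped",
           class = "other", baseScale = 0.05),
        df(gene = "KIN1", group = "ungrouped", class = "other",
           baseScale = 0.2))
}

defaultGroupParams <- function() {
    list(
        # exponential decline from the floral transition; half-life in
        # stage units
        set1 = list(halfLife = 0.5,
                    resurgenceCenter = 9.5, resurgenceWidth = 0.5,
                    resurgenceHeight = 0.8),
        # logistic rise from floral-organ initiation, sharp post-pollination
        # drop after W9.75
        set2 = list(onset = 5.5, width = 0.9, dropAfter = 9.75,
                    dropFactor = 0.12),
        # late logistic rise, still rising at the final stage
        set3 = list(midpoint = 9.0, width = 0.8),
        # shared broad early bump on a raised baseline; per-member fixed
        # orthogonal distortions pin within-group correlation near
        # `cohesion`
        pseudoset = list(center = 2.5, width = 1.0, baseline = 0.3,
                         cohesion = 0.83),
        # independent noise profiles, decorrelated from the pseudoset trend
        ungrouped = list(logSd = 0.5))
}

defaultReferencePanel <- function() {
    data.frame(
        gene = c("CYC", "TUB", "HSP70", "GAP"),
        conditionSd = c(0.15, 0.15, 0.15, 1.2),
        stringsAsFactors = FALSE)
}

#' Construct a synthetic-study configuration
#'
#' All arguments default to the emulated study conditions; see
#' [SimConfig-class] for their meaning.  When \code{nGenesPerGroup} differs
#' from the default sizes, genes are auto-named \code{<group>.<i>} with
#' class \code{"other"} and the overlap pair and injected organ deviations
#' are dropped unless re-specified.
#'
#' @param nGenesPerGroup Named integer vector of genes per group, e.g.
#'   \code{c(set1 = 3, set2 = 6, set3 = 7, pseudoset = 6, ungrouped = 4)}.
#'   \code{NULL} keeps the default named roster.
#' @param genes Full roster data.frame overriding \code{nGenesPerGroup}.
#' @param stageGrid,organs,groupParams,referencePanel See
#'   [SimConfig-class].
#' @param replicateSd Technical-replicate Cq noise in cycles (default 0.15,
#'   a typical qPCR technical spread).
#' @param biologicalJitterSd,pseudoJitterSd,scaleSd,organNoiseSd Noise
#'   parameters; see [SimConfig-class].
#' @param baseCq Cq corresponding to relative expression 1.0 (default 22;
#'   arbitrary anchor that cancels in normalization).
#' @param overlapPair Named character \code{c(target=, background=)} or
#'   \code{character(0)}.
#' @param resurgenceEnabled Enable the optional late second peak on the
#'   first set1 gene (default \code{FALSE}).
#' @param expressionFloor Missing-Cq floor as a fraction of the gene
#'   maximum (default \code{2^-15}).
#' @param organDeviations Injected off-model organ weights; the default
#'   adds C-class expression in the lodicules (an off-model pattern the
#'   conformance reporter must flag).
#' @param nReplicates Technical replicates (default 3).
#'
#' @return A validated [SimConfig-class] object.
#' @seealso [generateTruth()], [truthToCq()], [simulateCqDataset()]
#' @export
#' @examples
#' cfg <- simConfig()
#' table(cfg@genes$group)
simConfig <- function(nGenesPerGroup = NULL,
                      genes = NULL,
                      stageGrid = defaultStageGrid(),
                      organs = floralOrgans(),
                      groupParams = defaultGroupParams(),
                      referencePanel = defaultReferencePanel(),
                      replicateSd = 0.15,
                      biologicalJitterSd = 0.05,
                      pseudoJitterSd = 0.08,
                      scaleSd = 0.3,
                      baseCq = 22,
                      overlapPair = c(target = "PI1", background = "KIN1"),
                      resurgenceEnabled = FALSE,
                      expressionFloor = 2^-15,
                      organNoiseSd = 0.2,
                      organDeviations = data.frame(
                          gene = "AG2", organ = "lodicule", weight = 0.5,
                          stringsAsFactors = FALSE),
                      nReplicates = 3L) {
    if (is.null(genes)) {
        if (is.null(nGenesPerGroup)) {
            genes <- defaultGeneRoster()
        } else {
            bad <- setdiff(names(nGenesPerGroup),
                           c("set1", "set2", "set3", "pseudoset", "ungrouped"))
            if (length(bad))
                stop("invalid group name in nGenesPerGroup: ",
                     paste(bad, collapse = ", "))
            genes <- do.call(rbind, lapply(names(nGenesPerGroup), function(g) {
                n <- nGenesPerGroup[[g]]
                if (n < 0) stop("negative gene count for group ", g)
                if (n == 0) return(NULL)
                data.frame(gene = paste0(g, ".", seq_len(n)), group = g,
                           class = "other", baseScale = 1.0,
                           stringsAsFactors = FALSE)
            }))
            keep <- overlapPair[overlapPair %in% genes$gene]
            overlapPair <- if (length(keep) == 2L) overlapPair else character(0)
            organDeviations <- organDeviations[
                organDeviations$gene %in% genes$gene, , drop = FALSE]
        }
    }
    methods::new("SimConfig", genes = genes, stageGrid = stageGrid,
        organs = organs, groupParams = groupParams,
        referencePanel = referencePanel, replicateSd = replicateSd,
        biologicalJitterSd = biologicalJitterSd,
        pseudoJitterSd = pseudoJitterSd, scaleSd = scaleSd, baseCq = baseCq,
        overlapPair = overlapPair, resurgenceEnabled = resurgenceEnabled,
        expressionFloor = expressionFloor, organNoiseSd = organNoiseSd,
        organDeviations = organDeviations,
        nReplicates = as.integer(nReplicates))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", nrow(object@genes), "target assays +",
        nrow(object@referencePanel), "reference candidates\n")
    print(table(object@genes$group))
    cat("  replicateSd:", object@replicateSd, "cycles; baseCq:",
        object@baseCq, "\n")
    if (length(object@overlapPair))
        cat("  overlap pair:", object@overlapPair[["target"]], "over",
            object@overlapPair[["background"]], "\n")
})
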