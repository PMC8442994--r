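# End-to-end convenience wrappers: normalize -> correct -> correlate ->
# assign sets, and a ground-truth recovery harness for the synthetic
# generator.

#' Run the full co-expression pipeline on a Cq table
#'
#' Normalizes the raw Cq table per condition batch (selecting the best
#' \code{k} references from the panel), applies the antisense-overlap
#' correction when a pair is given, computes the time-course Pearson
#' matrix, assigns correlation sets and detects the pseudoset.
#'
#' @param cq A [CqTable-class].
#' @param panel Reference candidate names.
#' @param overlapPair Named character \code{c(target=, background=)} or
#'   \code{NULL} for no correction.
#' @param normP [normParams()] (its \code{panel} is overridden by
#'   \code{panel}).
#' @param setP [setRuleParams()].
#'
#' @return A list with elements \code{expr} ([RelExpressionSet-class]),
#'   \code{corr} (correlation matrix), \code{assignment}
#'   ([SetAssignment-class]) and \code{refs} (references selected per
#'   batch).
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 42)
#' res <- runCoexpressionPipeline(sim$cq,
#'     panel = c("CYC", "TUB", "HSP70", "GAP"),
#'     overlapPair = c(target = "PI1", background = "KIN1"))
#' res$assignment
runCoexpressionPipeline <- function(cq, panel,
                                    overlapPair = NULL,
                                    normP = normParams(),
                                    setP = setRuleParams()) {
    normP$panel <- panel
    expr <- normalizeCq(cq, normP)
    if (!is.null(overlapPair) && length(overlapPair))
        expr <- subtractOverlap(expr, overlapPair[["target"]],
                                overlapPair[["background"]])
    corr <- pearsonMatrix(expr)
    assignment <- assignSets(corr, expr, setP)
    assignment <- detectPseudoset(corr, assignment, expr, setP)
    list(expr = expr, corr = corr, assignment = assignment,
         refs = S4Vectors::metadata(expr)$refs)
}

#' Cross-check the set assignment with hierarchical clustering
#'
#' Clusters the genes that the correlation-set rule grouped (sets plus
#' pseudoset) with [hierarchicalCluster()] and measures agreement with the
#' set labels by adjusted Rand index.  Ungrouped genes carry no grouping
#' to agree on and are left out of the comparison.
#'
#' @param expr A [RelExpressionSet-class].
#' @param assignment A [SetAssignment-class].
#' @param k Number of clusters; defaults to the number of sets plus one
#'   for the pseudoset.
#'
#' @return A list with \code{ari} and the cluster \code{labels}.
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 42)
#' res <- runCoexpressionPipeline(sim$cq,
#'     panel = c("CYC", "TUB", "HSP70", "GAP"),
#'     overlapPair = c(target = "PI1", background = "KIN1"))
#' crossCheckClustering(res$expr, res$assignment)$ari
crossCheckClustering <- function(expr, assignment, k = NULL) {
    labels <- setLabels(assignment)
    grouped <- names(labels)[labels != "ungrouped"]
    if (is.null(k)) k <- length(unique(labels[grouped]))
    cl <- hierarchicalCluster(expr[grouped, ], k = k)
    list(ari = compareGroupings(cl, labels[names(cl)]), labels = cl)
}

#' Simulate a dataset and measure ground-truth recovery
#'
#' Generates a synthetic dataset, runs the full pipeline and compares the
#' recovered partition (sets, pseudoset, ungrouped) against the
#' generator's ground truth with the adjusted Rand index.
#'
#' @param config A [simConfig()].
#' @param seed Integer seed.
#' @param setP [setRuleParams()].
#' @param normP [normParams()].
#'
#' @return A list with \code{ari}, \code{nSets}, \code{assignment},
#'   \code{truth}, and the pipeline's \code{expr}/\code{corr}/\code{refs}.
#' @export
#' @examples
#' simulateAndRecover(simConfig(), seed = 42)$ari
simulateAndRecover <- function(config, seed, setP = setRuleParams(),
                               normP = normParams()) {
    sim <- simulateCqDataset(config, seed)
    res <- runCoexpressionPipeline(sim$cq,
        panel = config@referencePanel$gene,
        overlapPair = if (length(config@overlapPair)) config@overlapPair,
        normP = normP, setP = setP)
    labels <- setLabels(res$assignment)
    truthLabels <- groupOf(sim$truth)[names(labels)]
    nSets <- length(grep("^set_", unique(labels)))
    list(ari = compareGroupings(labels, truthLabels), nSets = nSets,
         assignment = res$assignment, truth = sim$truth, expr = res$expr,
         corr = res$corr, refs = res$refs)
}
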