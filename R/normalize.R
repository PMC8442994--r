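# Reference stability scoring, best-k selection and delta-Cq relative
# quantification.

#' Normalization parameters
#'
#' @param efficiency Amplification efficiency as fold change per cycle
#'   (default 2.0, i.e. perfect doubling).
#' @param panel Candidate reference gene names.
#' @param k Number of references to retain (default 3).
#' @param refAveraging How the reference relative quantities are combined
#'   into the normalization factor: \code{"arithmetic"} (default) or
#'   \code{"geometric"} mean.
#'
#' @return A list of class \code{"normParams"}.
#' @export
normParams <- function(efficiency = 2.0, panel = character(0), k = 3L,
                       refAveraging = c("arithmetic", "geometric")) {
    if (efficiency <= 1) stop("efficiency must be > 1")
    if (length(panel) && (k < 1 || k > length(panel)))
        stop("k must satisfy 1 <= k <= length(panel)")
    structure(list(efficiency = efficiency, panel = panel, k = as.integer(k),
                   refAveraging = match.arg(refAveraging)),
              class = "normParams")
}

# mean Cq per (gene, condition) over replicates, for the given condition
# type; genes with no amplification anywhere keep NA
conditionMeanCq <- function(cq, genes, type) {
    r <- cqRecords(cq)
    r <- r[r$conditionType == type & r$gene %in% genes, , drop = FALSE]
    if (!nrow(r)) stop("no '", type, "' measurements for the given genes")
    tapply(r$cq, list(r$gene, r$condition), mean)[genes, , drop = FALSE]
}

#' Score reference-gene stability (geNorm-style pairwise variation)
#'
#' For each candidate the score is the mean, over all other candidates, of
#' the standard deviation across conditions of the pairwise Cq difference.
#' A perfectly co-varying pair has constant difference and contributes 0;
#' lower scores mean more stable candidates.
#'
#' @param cq A [CqTable-class].
#' @param panel Candidate reference gene names (at least 2).
#' @param type Condition batch to score on: \code{"stage"} or
#'   \code{"organ"}.
#'
#' @return Named numeric vector of stability scores (lower = more stable).
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 1)
#' scoreReferenceStability(sim$cq, c("CYC", "TUB", "HSP70", "GAP"))
scoreReferenceStability <- function(cq, panel, type = "stage") {
    stopifnot(is(cq, "CqTable"))
    if (length(panel) < 2) stop("need at least 2 reference candidates")
    m <- conditionMeanCq(cq, panel, type)
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop("reference candidate '", rownames(m)[bad[1]],
             "' has missing Cq in condition '", colnames(m)[bad[2]], "'")
    }
    scores <- vapply(seq_along(panel), function(i) {
        mean(vapply(seq_along(panel)[-i],
                    function(j) sd(m[i, ] - m[j, ]), 0))
    }, 0)
    setNames(scores, panel)
}

#' Select the best-matching reference genes
#'
#' Returns the \code{k} candidates with the lowest stability score, ties
#' broken by lexicographic gene name.
#'
#' @param scores Named numeric vector from [scoreReferenceStability()].
#' @param k Number of references to retain.
#'
#' @return Character vector of \code{k} reference gene names, most stable
#'   first.
#' @export
#' @examples
#' selectReferenceGenes(c(a = 0.1, b = 0.2, c = 0.3, d = 0.9), k = 3)
selectReferenceGenes <- function(scores, k) {
    if (k > length(scores)) stop("k exceeds the number of scored candidates")
    names(scores)[order(scores, names(scores))][seq_len(k)]
}

#' Normalize a Cq table into relative expression
#'
#' Delta-Cq relative quantification: per replicate and condition, each
#' gene's relative quantity is \eqn{E^{-Cq}}; the normalization factor is
#' the average of the reference genes' relative quantities in that same
#' reaction set; the normalized value is their ratio.  Replicates are
#' normalized individually and then aggregated into a mean and a standard
#' deviation.  Stage and organ conditions are normalized as separate
#' batches and, when \code{refs} is \code{NULL}, references are re-selected
#' per batch from \code{params$panel}.  A missing Cq contributes quantity
#' 0; a gene missing in all replicates of a condition gets mean 0 and sd 0.
#'
#' @param cq A [CqTable-class].
#' @param params A [normParams()] object; its \code{panel} is used for
#'   per-batch reference selection when \code{refs} is \code{NULL}.
#' @param refs Explicit reference gene names to use for all batches, or
#'   \code{NULL} to score and select per batch.
#'
#' @return A [RelExpressionSet-class] over all conditions in \code{cq}
#'   (reference genes excluded from the rows).  The references used per
#'   batch are stored in \code{metadata(x)$refs}.
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 1)
#' expr <- normalizeCq(sim$cq, normParams(panel = c("CYC", "TUB", "HSP70", "GAP")))
#' expr
normalizeCq <- function(cq, params = normParams(), refs = NULL) {
    stopifnot(is(cq, "CqTable"))
    r <- cqRecords(cq)
    if (is.null(refs) && !length(params$panel))
        stop("either explicit refs or a candidate panel is required")
    types <- intersect(c("stage", "organ"), unique(r$conditionType))
    out <- list(); refsUsed <- list()
    for (type in types) {
        rt <- r[r$conditionType == type, , drop = FALSE]
        batchRefs <- refs
        if (is.null(batchRefs)) {
            sc <- scoreReferenceStability(cq, params$panel, type)
            batchRefs <- selectReferenceGenes(sc, params$k)
        }
        if (!length(batchRefs)) stop("empty reference set")
        out[[type]] <- normalizeBatch(rt, batchRefs, params,
                                      dropGenes = params$panel)
        refsUsed[[type]] <- batchRefs
    }
    meanM <- do.call(cbind, lapply(out, `[[`, "mean"))
    sdM <- do.call(cbind, lapply(out, `[[`, "sd"))
    condType <- rep(types, vapply(out, function(o) ncol(o$mean), 0L))
    sv <- ifelse(condType == "stage",
                 suppressWarnings(as.numeric(sub("^W", "", colnames(meanM)))),
                 NA_real_)
    ord <- order(match(condType, c("stage", "organ")), sv,
                 match(colnames(meanM), floralOrgans()))
    x <- RelExpressionSet(meanM[, ord, drop = FALSE],
                          sdM[, ord, drop = FALSE],
                          condType[ord], sv[ord])
    S4Vectors::metadata(x)$refs <- refsUsed
    x
}

# one condition-type batch: normalize each replicate, then aggregate.
# All panel candidates (used or not) are dropped from the output rows:
# reference candidates are not analysis targets.
normalizeBatch <- function(rt, refs, params, dropGenes = refs) {
    conds <- unique(rt$condition)
    reps <- sort(unique(rt$replicate))
    allGenes <- unique(rt$gene)
    genes <- setdiff(allGenes, union(refs, dropGenes))
    missingRef <- setdiff(refs, allGenes)
    if (length(missingRef))
        stop("reference gene(s) absent from this batch: ",
             paste(missingRef, collapse = ", "))
    E <- params$efficiency
    # quantity array: gene x condition x replicate, missing Cq -> 0
    q <- array(0, c(length(allGenes), length(conds), length(reps)),
               dimnames = list(allGenes, conds, reps))
    has <- !is.na(rt$cq)
    q[cbind(match(rt$gene, allGenes), match(rt$condition, conds),
            match(rt$replicate, reps))[has, , drop = FALSE]] <-
        E^(-rt$cq[has])
    normed <- array(NA_real_, c(length(genes), length(conds), length(reps)),
                    dimnames = list(genes, conds, reps))
    for (j in seq_along(reps)) {
        refQ <- matrix(q[refs, , j], nrow = length(refs),
                       dimnames = list(refs, conds))
        if (any(refQ == 0)) {
            bad <- which(colSums(refQ == 0) > 0)[1]
            stop("reference gene missing in condition '", conds[bad], "'")
        }
        nf <- if (params$refAveraging == "arithmetic") colMeans(refQ)
              else exp(colMeans(log(refQ)))
        gq <- matrix(q[genes, , j], nrow = length(genes),
                     dimnames = list(genes, conds))
        normed[, , j] <- sweep(gq, 2, nf, "/")
    }
    list(mean = apply(normed, c(1, 2), mean),
         sd = apply(normed, c(1, 2), sd))
}

#' Subtract an overlapping background assay from an observed assay
#'
#' When a target transcript is fully covered by a transcript from the
#' opposite strand, its primer pair amplifies both and the assay observes
#' target plus background.  Subtracting a background-only assay recovers
#' the target: corrected \eqn{Q = \max(0, Q_{obs} - Q_{bg})} per condition,
#' with the replicate sd propagated as
#' \eqn{\sqrt{sd_{obs}^2 + sd_{bg}^2}}.
#'
#' @param x A [RelExpressionSet-class] containing both assays, or a
#'   single-gene [RelExpressionSet-class] (the observed row) when
#'   \code{background} is itself a single-gene [RelExpressionSet-class]
#'   over the same conditions.
#' @param observed,background Gene names in \code{x} (first form), or
#'   omitted (second form).
#' @param newName Optional new row name for the corrected assay; default
#'   keeps the observed name.
#'
#' @return \code{x} with the observed row replaced by the corrected row
#'   (first form), or a single-row corrected [RelExpressionSet-class]
#'   (second form).
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 1)
#' expr <- normalizeCq(sim$cq, normParams(panel = c("CYC", "TUB", "HSP70", "GAP")))
#' corrected <- subtractOverlap(expr, "PI1", "KIN1")
subtractOverlap <- function(x, observed, background, newName = NULL) {
    stopifnot(is(x, "RelExpressionSet"))
    if (is(background, "RelExpressionSet")) {
        if (nrow(x) != 1L || nrow(background) != 1L)
            stop("row-wise form expects single-gene objects")
        if (!identical(colnames(x), colnames(background)))
            stop("observed and background rows have mismatched conditions")
        bg <- background
        obs <- rownames(x)[1]
        y <- x
    } else {
        miss <- setdiff(c(observed, background), rownames(x))
        if (length(miss))
            stop("gene(s) not present: ", paste(miss, collapse = ", "))
        bg <- x[background, ]
        obs <- observed
        y <- x
    }
    m <- meanQ(y); s <- sdQ(y)
    m[obs, ] <- pmax(0, m[obs, ] - meanQ(bg)[1, ])
    s[obs, ] <- sqrt(s[obs, ]^2 + sdQ(bg)[1, ]^2)
    SummarizedExperiment::assay(y, "meanQ") <- m
    SummarizedExperiment::assay(y, "sdQ") <- s
    if (!is.null(newName))
        rownames(y)[rownames(y) == obs] <- newName
    y
}
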