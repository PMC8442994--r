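# Pearson co-expression analysis: correlation matrix, threshold-graph set
# rule (m-core), pseudoset detection and a hierarchical-clustering
# cross-check.

#' Parameters of the correlation-set rule
#'
#' @param tau Primary threshold: a qualifying partnership needs Pearson
#'   r strictly above \code{tau} (default 0.9).
#' @param m Minimum number of qualifying within-set partners per member
#'   (default 2, i.e. "r > 0.9 with at least two other members").
#' @param tau2 Secondary threshold for the looser pseudoset (default 0.75).
#' @param minSetSize Minimum genes per set or pseudoset (default 3).
#' @param partnerScope \code{"members"} (default) requires the partners to
#'   be set members themselves, i.e. the m-core of the thresholded graph;
#'   \code{"all"} is the looser reading where any gene can serve as a
#'   partner.
#'
#' @return A list of class \code{"setRuleParams"}.
#' @export
setRuleParams <- function(tau = 0.9, m = 2L, tau2 = 0.75, minSetSize = 3L,
                          partnerScope = c("members", "all")) {
    if (!(-1 < tau2 && tau2 <= tau && tau < 1))
        stop("need -1 < tau2 <= tau < 1")
    if (m < 1) stop("m must be >= 1")
    structure(list(tau = tau, m = as.integer(m), tau2 = tau2,
                   minSetSize = as.integer(minSetSize),
                   partnerScope = match.arg(partnerScope)),
              class = "setRuleParams")
}

#' Pearson correlation matrix over the developmental time course
#'
#' Standard product-moment correlation of per-gene mean profiles over the
#' time-course conditions (the organ panel is never used for set
#' assignment).  Zero-variance profiles have undefined correlation and
#' yield missing values against all partners; missing values are never
#' treated as exceeding a threshold downstream.
#'
#' @param expr A [RelExpressionSet-class].
#'
#' @return Symmetric genes-by-genes matrix with unit diagonal; \code{NA}
#'   off-diagonal where r is undefined.
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 1)
#' expr <- normalizeCq(sim$cq, normParams(panel = c("CYC", "TUB", "HSP70", "GAP")))
#' r <- pearsonMatrix(expr)
#' r[1:3, 1:3]
pearsonMatrix <- function(expr) {
    m <- meanQ(timeCourse(expr))
    if (ncol(m) < 3) stop("need at least 3 time-course conditions")
    r <- suppressWarnings(cor(t(m)))
    diag(r) <- 1
    r
}

#' The m-core of an adjacency matrix
#'
#' Iteratively deletes nodes of degree < m until a fixpoint; the result is
#' the unique maximal subgraph in which every node has at least \code{m}
#' neighbours, independent of deletion order.
#'
#' @param adj Logical symmetric adjacency matrix (no self-edges assumed).
#' @param m Minimum degree.
#'
#' @return Logical vector: membership of each node in the m-core.
#' @export
#' @examples
#' adj <- matrix(TRUE, 3, 3); diag(adj) <- FALSE
#' mCore(adj, 2)
mCore <- function(adj, m) {
    keep <- rep(TRUE, nrow(adj))
    repeat {
        deg <- as.vector(adj %*% keep)
        drop <- keep & deg < m
        if (!any(drop)) break
        keep[drop] <- FALSE
    }
    setNames(keep, rownames(adj))
}

# connected components of a logical adjacency matrix; returns a list of
# index vectors
graphComponents <- function(adj) {
    n <- nrow(adj)
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (i in seq_len(n)) {
        if (!is.na(comp[i])) next
        nc <- nc + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (!is.na(comp[v])) next
            comp[v] <- nc
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    unname(split(seq_len(n), comp))
}

# stage label of maximum mean expression per gene (earliest tie wins);
# all-zero profiles give "none"
genePeakStages <- function(expr) {
    tc <- timeCourse(expr)
    m <- meanQ(tc)
    vapply(seq_len(nrow(m)), function(i) {
        if (all(m[i, ] == 0)) "none" else colnames(m)[which.max(m[i, ])]
    }, "", USE.NAMES = FALSE) |> setNames(rownames(m))
}

genePeakValues <- function(expr) {
    tc <- timeCourse(expr)
    m <- meanQ(tc)
    sv <- stageValues(tc)
    vapply(seq_len(nrow(m)), function(i) {
        if (all(m[i, ] == 0)) NA_real_ else sv[which.max(m[i, ])]
    }, 0) |> setNames(rownames(m))
}

#' Assign genes to correlation sets
#'
#' Implements the threshold-graph set rule: build a graph with an edge
#' wherever r is strictly above \code{tau}, take the m-core (iterated
#' deletion of nodes with fewer than \code{m} qualifying partners), and
#' call each connected component with at least \code{minSetSize} genes a
#' correlation set.  Sets are labelled \code{set_1 ... set_K} by ascending
#' mean peak stage of their members, so the earliest-expressed set is
#' always \code{set_1}.  Genes outside every set are labelled
#' \code{ungrouped}; pass the result to [detectPseudoset()] to split off
#' the looser pseudoset.
#'
#' @param corr Correlation matrix from [pearsonMatrix()].
#' @param expr The matching [RelExpressionSet-class] (for peak stages).
#' @param params [setRuleParams()].
#'
#' @return A [SetAssignment-class].
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 42)
#' expr <- normalizeCq(sim$cq, normParams(panel = c("CYC", "TUB", "HSP70", "GAP")))
#' expr <- subtractOverlap(expr, "PI1", "KIN1")
#' assignSets(pearsonMatrix(expr), expr)
assignSets <- function(corr, expr, params = setRuleParams()) {
    genes <- rownames(corr)
    adj <- !is.na(corr) & corr > params$tau
    diag(adj) <- FALSE
    core <- if (params$partnerScope == "members") {
        mCore(adj, params$m)
    } else {
        as.vector(adj %*% rep(TRUE, ncol(adj))) >= params$m
    }
    idx <- which(core)
    peaks <- genePeakValues(expr)[genes]
    sets <- list()
    if (length(idx)) {
        sub <- adj[idx, idx, drop = FALSE]
        comps <- graphComponents(sub)
        comps <- lapply(comps, function(ii) idx[ii])
        comps <- comps[vapply(comps, length, 0L) >= params$minSetSize]
        if (length(comps)) {
            meanPeak <- vapply(comps, function(ii) mean(peaks[ii], na.rm = TRUE), 0)
            firstGene <- vapply(comps, function(ii) min(genes[ii]), "")
            sets <- comps[order(meanPeak, firstGene)]
        }
    }
    labels <- setNames(rep("ungrouped", length(genes)), genes)
    nPartners <- setNames(integer(length(genes)), genes)
    for (k in seq_along(sets)) {
        ii <- sets[[k]]
        labels[ii] <- paste0("set_", k)
        nPartners[ii] <- as.integer(rowSums(adj[ii, ii, drop = FALSE]))
    }
    methods::new("SetAssignment", labels = labels, nPartners = nPartners,
                 peakStage = genePeakStages(expr)[genes],
                 params = unclass(params))
}

#' Detect the pseudoset among unassigned genes
#'
#' Among genes left ungrouped by [assignSets()], edges are drawn where r is
#' strictly above the secondary threshold \code{tau2}; connected components
#' with at least \code{minSetSize} genes are pseudoset candidates and the
#' largest one (ties broken by earliest mean peak stage) becomes THE
#' pseudoset.  All other unassigned genes stay ungrouped.
#'
#' @param corr Correlation matrix from [pearsonMatrix()].
#' @param assignment A [SetAssignment-class] from [assignSets()].
#' @param params [setRuleParams()].
#' @param expr The matching [RelExpressionSet-class] (for the tie-break).
#'
#' @return The updated [SetAssignment-class] with a \code{pseudoset}
#'   label where detected.
#' @export
detectPseudoset <- function(corr, assignment, expr,
                            params = setRuleParams()) {
    labels <- setLabels(assignment)
    rest <- names(labels)[labels == "ungrouped"]
    if (length(rest) < params$minSetSize) return(assignment)
    sub <- corr[rest, rest, drop = FALSE]
    adj <- !is.na(sub) & sub > params$tau2
    diag(adj) <- FALSE
    comps <- graphComponents(adj)
    comps <- comps[vapply(comps, length, 0L) >= params$minSetSize]
    if (!length(comps)) return(assignment)
    peaks <- genePeakValues(expr)[rest]
    sizes <- vapply(comps, length, 0L)
    meanPeak <- vapply(comps, function(ii) mean(peaks[ii], na.rm = TRUE), 0)
    best <- order(-sizes, meanPeak)[1]
    labels[rest[comps[[best]]]] <- "pseudoset"
    methods::new("SetAssignment", labels = labels,
                 nPartners = assignment@nPartners,
                 peakStage = assignment@peakStage, params = unclass(params))
}

#' Hierarchical clustering cross-check
#'
#' Clusters per-gene z-scored time-course profiles (mean 0, sd 1 per gene)
#' with Euclidean distance and complete linkage, and cuts the tree into
#' \code{k} clusters.  Zero-variance genes cannot be z-scored and are
#' excluded with a warning.
#'
#' @param expr A [RelExpressionSet-class].
#' @param k Number of clusters.
#'
#' @return Named integer vector of cluster labels (excluded genes absent).
#' @export
hierarchicalCluster <- function(expr, k) {
    stopifnot(k >= 1)
    m <- meanQ(timeCourse(expr))
    v <- apply(m, 1, sd)
    if (any(v == 0)) {
        warning("excluding zero-variance gene(s): ",
                paste(rownames(m)[v == 0], collapse = ", "))
        m <- m[v > 0, , drop = FALSE]
    }
    z <- t(scale(t(m)))
    cutree(hclust(dist(z), method = "complete"), k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same genes:
#' 1.0 for identical partitions and approximately 0 for independent ones.
#'
#' @param a,b Named label vectors over the same gene universe.
#'
#' @return The adjusted Rand index.
#' @export
#' @examples
#' compareGroupings(c(x = 1, y = 1, z = 2), c(x = "a", y = "a", z = "b"))
compareGroupings <- function(a, b) {
    if (is.null(names(a)) || is.null(names(b)) ||
        !setequal(names(a), names(b)))
        stop("partitions must be named over the same gene universe")
    b <- b[names(a)]
    tab <- table(a, b)
    n <- sum(tab)
    sumRow <- sum(choose(rowSums(tab), 2))
    sumCol <- sum(choose(colSums(tab), 2))
    sumCell <- sum(choose(tab, 2))
    expected <- sumRow * sumCol / choose(n, 2)
    denom <- (sumRow + sumCol) / 2 - expected
    if (denom == 0) return(1)      # both partitions degenerate and equal
    (sumCell - expected) / denom
}
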