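# Independent oracles used to cross-check the implementation.

defaultPanel <- c("CYC", "TUB", "HSP70", "GAP")

# Pearson r evaluated from the defining sum, with population sd
pearsonClosedForm <- function(x, y) {
    n <- length(x)
    sx <- sqrt(mean((x - mean(x))^2))
    sy <- sqrt(mean((y - mean(y))^2))
    sum((x - mean(x)) * (y - mean(y))) / (n * sx * sy)
}

# direct recomputation of the average pairwise-variation stability score
# from a candidate-by-condition matrix of mean Cq values
naiveStability <- function(m) {
    n <- nrow(m)
    vapply(seq_len(n), function(i) {
        mean(vapply(setdiff(seq_len(n), i),
                    function(j) sd(m[i, ] - m[j, ]), 0))
    }, 0) |> setNames(rownames(m))
}

# m-core by explicit deletion: removes deletable nodes one at a time in
# the order given by `pick` until the fixpoint
mCoreByDeletion <- function(adj, m, pick = function(cand) cand[1]) {
    keep <- rep(TRUE, nrow(adj))
    repeat {
        deg <- as.vector(adj %*% keep)
        cand <- which(keep & deg < m)
        if (!length(cand)) break
        keep[pick(cand)] <- FALSE
    }
    keep
}

# enumerate every deletion order recursively; returns the set of distinct
# cores reachable (should always be exactly one)
enumerateMCores <- function(adj, m, keep = rep(TRUE, nrow(adj))) {
    deg <- as.vector(adj %*% keep)
    cand <- which(keep & deg < m)
    if (!length(cand)) return(list(keep))
    out <- list()
    for (v in cand) {
        k2 <- keep; k2[v] <- FALSE
        out <- c(out, enumerateMCores(adj, m, k2))
    }
    unique(out)
}

# naive O(n^3) complete-linkage agglomeration; ties broken by the
# smallest pair of current cluster indices
naiveCompleteLinkage <- function(x, k) {
    n <- nrow(x)
    d <- as.matrix(dist(x))
    clusters <- as.list(seq_len(n))
    while (length(clusters) > k) {
        best <- NULL; bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            dd <- max(d[clusters[[i]], clusters[[j]]])
            if (dd < bestD - 1e-12) { bestD <- dd; best <- c(i, j) }
        }
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    lab <- integer(n)
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    setNames(lab, rownames(x))
}

# a tiny hand-built Cq table: genes x conditions matrix of mean Cq,
# expanded to `reps` identical (or jittered) replicates on the stage batch
cqFromMatrix <- function(m, reps = 3, type = "stage") {
    df <- expand.grid(gene = rownames(m), condition = colnames(m),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
    df$conditionType <- type
    df$cq <- m[cbind(df$gene, df$condition)]
    CqTable(records = df[c("gene", "conditionType", "condition",
                           "replicate", "cq")])
}
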