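# helper: wrap a profile matrix (genes x stages) as a RelExpressionSet
exprFromMatrix <- function(m) {
    colnames(m) <- paste0("W", seq_len(ncol(m)))
    RelExpressionSet(m, m * 0, "stage", seq_len(ncol(m)))
}

test_that("pearsonMatrix matches the closed-form definition", {
    x <- c(1, 2, 3, 4)
    y <- c(1, 2, 3, 10)
    m <- exprFromMatrix(rbind(a = x, b = y, c = -x + 10))
    r <- pearsonMatrix(m)
    expect_equal(diag(r), c(a = 1, b = 1, c = 1))
    expect_equal(r["a", "b"], pearsonClosedForm(x, y), tolerance = 1e-12)
    expect_equal(r["a", "c"], -1.0, tolerance = 1e-12)
    expect_equal(r, t(r))
})

test_that("zero-variance profiles give missing correlations, never edges", {
    m <- exprFromMatrix(rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 2, 1)))
    r <- pearsonMatrix(m)
    expect_true(is.na(r["a", "b"]) && is.na(r["b", "c"]))
    expect_equal(r["b", "b"], 1)
    asg <- assignSets(r, m)
    expect_identical(unname(setLabels(asg)["b"]), "ungrouped")
})

test_that("fewer than 3 time-course conditions is an error", {
    m <- RelExpressionSet(matrix(1:4, 2, dimnames = list(c("a", "b"), c("W1", "W2"))),
                          matrix(0, 2, 2, dimnames = list(c("a", "b"), c("W1", "W2"))),
                          "stage", 1:2)
    expect_error(pearsonMatrix(m), "at least 3")
})

test_that("a mutually correlated trio forms exactly one set", {
    base <- c(1, 2, 5, 9, 3)
    m <- exprFromMatrix(rbind(a = base, b = base * 2 + 0.01,
                              c = base * 0.5,
                              d = rev(base), e = c(9, 1, 8, 1, 9)))
    r <- pearsonMatrix(m)
    asg <- assignSets(r, m)
    expect_identical(setMembers(asg, "set_1"), c("a", "b", "c"))
    expect_identical(sort(names(setLabels(asg))[setLabels(asg) == "ungrouped"]),
                     c("d", "e"))
})

test_that("a chain without a cycle never survives the m-core", {
    # a-b and b-c edges, no a-c edge: every deletion order empties the core
    adj <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    adj["a", "b"] <- adj["b", "a"] <- TRUE
    adj["b", "c"] <- adj["c", "b"] <- TRUE
    cores <- enumerateMCores(adj, m = 2)
    expect_length(cores, 1)
    expect_identical(cores[[1]], rep(FALSE, 3))
    expect_identical(unname(mCore(adj, 2)), rep(FALSE, 3))
})

test_that("m-core equals exhaustive deletion-order enumeration on small graphs", {
    set.seed(42)
    for (rep in 1:25) {
        n <- sample(4:8, 1)
        adj <- matrix(runif(n * n) < 0.4, n, n)
        adj <- adj | t(adj); diag(adj) <- FALSE
        dimnames(adj) <- list(letters[1:n], letters[1:n])
        m <- sample(1:3, 1)
        cores <- enumerateMCores(adj, m)
        expect_length(cores, 1)   # fixpoint unique over ALL deletion orders
        expect_identical(unname(mCore(adj, m)), cores[[1]])
    }
    # larger graphs: randomized deletion orders agree with the implementation
    for (rep in 1:10) {
        n <- 12
        adj <- matrix(runif(n * n) < 0.3, n, n)
        adj <- adj | t(adj); diag(adj) <- FALSE
        ref <- unname(mCore(adj, 2))
        for (o in 1:20)
            expect_identical(
                mCoreByDeletion(adj, 2, pick = function(cand) sample(cand, 1)),
                ref)
    }
})

test_that("every set member has >= m within-set partners above tau", {
    cfg <- simConfig()
    for (s in c(1, 42, 77)) {
        r <- simulateAndRecover(cfg, s)
        lab <- setLabels(r$assignment)
        tau <- r$assignment@params$tau
        for (g in names(lab)[grepl("^set_", lab)]) {
            mem <- setdiff(names(lab)[lab == lab[g]], g)
            expect_gte(sum(r$corr[g, mem] > tau, na.rm = TRUE), 2)
        }
    }
})

test_that("assignment partitions the gene universe and orders sets by peak", {
    cfg <- simConfig()
    r <- simulateAndRecover(cfg, 42)
    lab <- setLabels(r$assignment)
    expect_setequal(names(lab), rownames(r$corr))
    expect_true(all(lab %in% c(paste0("set_", 1:3), "pseudoset", "ungrouped")))
    sv <- defaultStageGrid()@values
    names(sv) <- defaultStageGrid()@labels
    meanPeak <- vapply(paste0("set_", 1:3), function(s)
        mean(sv[r$assignment@peakStage[setMembers(r$assignment, s)]]), 0)
    expect_true(all(diff(meanPeak) > 0))
})

test_that("set labelling is invariant to gene input order", {
    cfg <- simConfig()
    sim <- simulateCqDataset(cfg, 13)
    res <- runCoexpressionPipeline(sim$cq, panel = defaultPanel,
                                   overlapPair = cfg@overlapPair)
    perm <- sample(rownames(res$expr))
    expr2 <- res$expr[perm, ]
    corr2 <- pearsonMatrix(expr2)
    asg2 <- detectPseudoset(corr2, assignSets(corr2, expr2), expr2)
    expect_identical(setLabels(res$assignment)[perm], setLabels(asg2))
})

test_that("pseudoset detection follows the secondary-threshold rule", {
    # no unassigned pair above tau2: everything stays ungrouped
    m <- exprFromMatrix(rbind(a = c(1, 5, 2, 8), b = c(5, 1, 8, 2),
                              c = c(1, 1, 9, 1)))
    r <- pearsonMatrix(m)
    asg <- detectPseudoset(r, assignSets(r, m), m)
    expect_true(all(setLabels(asg) == "ungrouped"))

    # five genes pairwise exactly r = 0.8: all five become the pseudoset.
    # Construction: shared trend plus centered orthonormal distortions of
    # equal amplitude, which makes every pairwise r identical.
    u <- c(1, 4, 9, 5, 2, 1, 0.5)
    Q <- qr.Q(qr(cbind(1, u - mean(u), stats::contr.helmert(7))))[, 3:7]
    a <- sqrt(6 * var(u) * (1 - 0.8) / 0.8)
    mm <- 10 + t(vapply(1:5, function(i) u + a * Q[, i], u))
    rownames(mm) <- letters[1:5]
    m <- exprFromMatrix(mm)
    r <- pearsonMatrix(m)
    expect_equal(unname(r[upper.tri(r)]), rep(0.8, 10), tolerance = 1e-9)
    asg <- detectPseudoset(r, assignSets(r, m), m)
    expect_true(all(setLabels(asg) == "pseudoset"))
})

test_that("pseudoset and ungrouped genes are recovered from ground truth", {
    cfg <- simConfig()
    r <- simulateAndRecover(cfg, 42)
    truth <- groupOf(r$truth)
    expect_setequal(setMembers(r$assignment, "pseudoset"),
                    names(truth)[truth == "pseudoset"])
    expect_setequal(setMembers(r$assignment, "ungrouped"),
                    names(truth)[truth == "ungrouped"])
})

test_that("complete-linkage clustering matches the naive agglomerator", {
    set.seed(9)
    # two obvious blocks of three
    m <- rbind(matrix(rnorm(15, 10), 3), matrix(rnorm(15, 18), 3))
    rownames(m) <- letters[1:6]
    e <- exprFromMatrix(m)
    got <- hierarchicalCluster(e, k = 2)
    want <- naiveCompleteLinkage(t(scale(t(m))), 2)
    expect_equal(compareGroupings(got, want), 1.0)
    # larger random instances against the O(n^3) oracle
    for (rep in 1:5) {
        m <- matrix(rnorm(10 * 6, 10), 10, dimnames = list(letters[1:10], NULL))
        e <- exprFromMatrix(m)
        for (k in c(2, 4)) {
            got <- hierarchicalCluster(e, k = k)
            want <- naiveCompleteLinkage(t(scale(t(m))), k)
            expect_equal(compareGroupings(got, want), 1.0)
        }
    }
})

test_that("identical genes merge first and zero variance is excluded", {
    m <- rbind(a = c(1, 5, 2), b = c(1, 5, 2), c = c(9, 1, 4),
               flat = c(2, 2, 2))
    e <- exprFromMatrix(m)
    expect_warning(cl <- hierarchicalCluster(e, k = 2), "flat")
    expect_false("flat" %in% names(cl))
    expect_equal(cl[["a"]], cl[["b"]])
})

test_that("clustering cross-checks the correlation sets", {
    r <- simulateAndRecover(simConfig(), 42)
    cc <- crossCheckClustering(r$expr, r$assignment, k = 4)
    expect_gte(cc$ari, 0.8)
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
    a <- setNames(rep(1:2, each = 5), letters[1:10])
    expect_equal(compareGroupings(a, a), 1.0)
    singletons <- setNames(1:10, letters[1:10])
    lump <- setNames(rep(1, 10), letters[1:10])
    expect_equal(compareGroupings(singletons, lump), 0.0)
    expect_error(compareGroupings(a, setNames(1:3, c("a", "b", "zz"))),
                 "universe")
    # permutation null: mean ARI ~ 0 within 3 standard errors
    set.seed(11)
    base <- setNames(rep(1:4, each = 5), paste0("g", 1:20))
    draws <- vapply(seq_len(10000), function(i)
        compareGroupings(base, setNames(sample(base), names(base))), 0)
    expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
    # agrees with an independent implementation
    skip_if_not_installed("mclust")
    for (i in 1:20) {
        x <- setNames(sample(1:3, 12, TRUE), paste0("g", 1:12))
        y <- setNames(sample(1:4, 12, TRUE), paste0("g", 1:12))
        expect_equal(compareGroupings(x, y),
                     mclust::adjustedRandIndex(x, y[names(x)]),
                     tolerance = 1e-12)
    }
})
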