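stageNames <- paste0("W", 1:8)

test_that("pairwise-variation stability scoring matches its definition", {
    # two candidates offset by a constant have zero pairwise variation
    m <- rbind(a = 1:8 + 20, b = 1:8 + 22)
    colnames(m) <- stageNames
    sc <- scoreReferenceStability(cqFromMatrix(m), c("a", "b"))
    expect_equal(unname(sc), c(0, 0))

    # three collinear candidates plus one independently jittered one:
    # the jittered candidate scores strictly worst, and all scores match
    # a direct recomputation
    set.seed(1)
    base <- rnorm(8, 22, 1)
    m <- rbind(a = base, b = base + 1, c = base - 2,
               d = base + rnorm(8, 0, 1))
    colnames(m) <- stageNames
    sc <- scoreReferenceStability(cqFromMatrix(m), letters[1:4])
    expect_equal(sc, naiveStability(m))
    expect_identical(names(which.max(sc)), "d")
    expect_true(sc["d"] > max(sc[c("a", "b", "c")]))
})

test_that("stability scoring reports the missing candidate and condition", {
    m <- rbind(a = 1:4 + 20, b = 1:4 + 21)
    colnames(m) <- paste0("W", 1:4)
    m["b", "W3"] <- NA
    expect_error(scoreReferenceStability(cqFromMatrix(m), c("a", "b")),
                 "'b'.*'W3'")
})

test_that("reference selection takes the k lowest scores, ties lexicographic", {
    expect_identical(
        selectReferenceGenes(c(a = 0.1, b = 0.2, c = 0.3, d = 0.9), 3),
        c("a", "b", "c"))
    expect_identical(
        selectReferenceGenes(c(d = 0.5, b = 0.5, c = 0.5, a = 0.5), 3),
        c("a", "b", "c"))
    expect_error(selectReferenceGenes(c(a = 1, b = 2), 3), "exceeds")
})

test_that("the destabilized panel candidate ranks last and is excluded", {
    cfg <- simConfig()
    cq <- simulateCqDataset(cfg, seed = 5)$cq
    for (type in c("stage", "organ")) {
        sc <- scoreReferenceStability(cq, defaultPanel, type)
        expect_identical(names(which.max(sc)), "GAP")
        refs <- selectReferenceGenes(sc, 3)
        expect_length(refs, 3)
        expect_false("GAP" %in% refs)
    }
})

test_that("delta-Cq normalization follows the arithmetic-mean NF model", {
    # target identical to both references -> Q = 1 everywhere, sd = 0
    m <- rbind(g = rep(21, 5), r1 = rep(21, 5), r2 = rep(21, 5))
    colnames(m) <- paste0("W", 1:5)
    e <- normalizeCq(cqFromMatrix(m), refs = c("r1", "r2"),
                     params = normParams(panel = c("r1", "r2"), k = 2))
    expect_equal(unname(meanQ(e)["g", ]), rep(1, 5))
    expect_equal(unname(sdQ(e)["g", ]), rep(0, 5))

    # one cycle below the references doubles the quantity at E = 2
    m["g", ] <- 20
    e <- normalizeCq(cqFromMatrix(m), refs = c("r1", "r2"))
    expect_equal(unname(meanQ(e)["g", ]), rep(2, 5))

    # refs at Cq 20 and 22, target at 20: Q = 2^-20 / mean(2^-20, 2^-22)
    m <- rbind(g = rep(20, 5), r1 = rep(20, 5), r2 = rep(22, 5))
    colnames(m) <- paste0("W", 1:5)
    e <- normalizeCq(cqFromMatrix(m), refs = c("r1", "r2"))
    expect_equal(unname(meanQ(e)["g", ]), rep(1.6, 5), tolerance = 1e-12)
})

test_that("missing target Cq contributes quantity zero", {
    m <- rbind(g = c(20, NA, 20), r1 = rep(20, 3))
    colnames(m) <- paste0("W", 1:3)
    cq <- cqFromMatrix(m, reps = 1)
    e <- normalizeCq(cq, refs = "r1")
    expect_equal(unname(meanQ(e)["g", ]), c(1, 0, 1))
    # missing in one of three replicates pulls the mean to 2/3
    m3 <- rbind(g = rep(20, 3), r1 = rep(20, 3))
    colnames(m3) <- paste0("W", 1:3)
    r <- cqRecords(cqFromMatrix(m3, reps = 3))
    r$cq[r$gene == "g" & r$condition == "W2" & r$replicate == 2] <- NA
    e3 <- normalizeCq(CqTable(records = r), refs = "r1")
    expect_equal(unname(meanQ(e3)["g", "W2"]), 2 / 3)
})

test_that("missing reference measurements are an error", {
    m <- rbind(g = rep(20, 3), r1 = c(20, NA, 20))
    colnames(m) <- paste0("W", 1:3)
    expect_error(normalizeCq(cqFromMatrix(m), refs = "r1"),
                 "reference gene missing")
    expect_error(normalizeCq(cqFromMatrix(m), refs = character(0)),
                 "empty reference")
})

test_that("normalization is shift-invariant under a per-condition Cq offset", {
    cfg <- simConfig()
    cq <- simulateCqDataset(cfg, seed = 3)$cq
    r <- cqRecords(cq)
    offsets <- setNames(runif(length(unique(r$condition)), -2, 2),
                        unique(r$condition))
    r2 <- r
    r2$cq <- r2$cq + offsets[r2$condition]
    e1 <- normalizeCq(cq, normParams(panel = defaultPanel))
    e2 <- normalizeCq(CqTable(records = r2), normParams(panel = defaultPanel))
    expect_equal(meanQ(e1), meanQ(e2), tolerance = 1e-9)
})

test_that("decreasing a target's Cq strictly increases its Q", {
    m <- rbind(g = rep(21, 4), r1 = rep(20, 4))
    colnames(m) <- paste0("W", 1:4)
    qs <- vapply(c(21, 20.5, 19, 15), function(cqv) {
        m["g", ] <- cqv
        meanQ(normalizeCq(cqFromMatrix(m), refs = "r1"))["g", 1]
    }, 0)
    expect_true(all(diff(qs) > 0))
})

test_that("organ and stage batches are normalized independently", {
    cfg <- simConfig()
    cq <- simulateCqDataset(cfg, seed = 4)$cq
    r <- cqRecords(cq)
    e1 <- normalizeCq(cq, normParams(panel = defaultPanel))
    # permuting organ-batch rows must not change time-course values
    org <- which(r$conditionType == "organ")
    r2 <- rbind(r[-org, ], r[rev(org), ])
    e2 <- normalizeCq(CqTable(records = r2), normParams(panel = defaultPanel))
    expect_equal(meanQ(timeCourse(e1)), meanQ(timeCourse(e2)))
})

test_that("replicate sd is invariant to replicate order", {
    m <- rbind(g = rep(20, 3), r1 = rep(20, 3))
    colnames(m) <- paste0("W", 1:3)
    r <- cqRecords(cqFromMatrix(m, reps = 3))
    r$cq[r$gene == "g"] <- r$cq[r$gene == "g"] + c(-0.3, 0, 0.3)
    e1 <- normalizeCq(CqTable(records = r), refs = "r1")
    r2 <- r
    r2$replicate[r$gene == "g"] <- 4 - r$replicate[r$gene == "g"]
    e2 <- normalizeCq(CqTable(records = r2), refs = "r1")
    expect_equal(sdQ(e1), sdQ(e2))
})

test_that("overlap subtraction clips at zero and propagates sd", {
    mk <- function(obs, bg) {
        RelExpressionSet(
            meanQ = rbind(obs = obs, bg = bg),
            sdQ = rbind(obs = rep(0.3, length(obs)),
                        bg = rep(0.4, length(bg))),
            conditionType = "stage",
            stageValue = seq_along(obs)) |>
            (\(x) { colnames(x) <- paste0("W", seq_along(obs)); x })()
    }
    x <- mk(c(5, 2, 1), c(0, 0, 0))
    y <- subtractOverlap(x, "obs", "bg")
    expect_equal(unname(meanQ(y)["obs", ]), c(5, 2, 1))
    x <- mk(c(1, 2, 3), c(2, 2, 3))
    y <- subtractOverlap(x, "obs", "bg")
    expect_equal(unname(meanQ(y)["obs", ]), c(0, 0, 0))
    expect_equal(unname(sdQ(y)["obs", ]), rep(sqrt(0.09 + 0.16), 3))
})

test_that("row-wise overlap subtraction rejects mismatched conditions", {
    a <- RelExpressionSet(matrix(1, 1, 3, dimnames = list("x", paste0("W", 1:3))),
                          matrix(0, 1, 3, dimnames = list("x", paste0("W", 1:3))),
                          "stage", 1:3)
    b <- RelExpressionSet(matrix(1, 1, 3, dimnames = list("y", paste0("W", 4:6))),
                          matrix(0, 1, 3, dimnames = list("y", paste0("W", 4:6))),
                          "stage", 4:6)
    expect_error(subtractOverlap(a, background = b), "mismatched conditions")
})

test_that("synthetic overlap pair round-trips at zero noise", {
    cfg <- simConfig(replicateSd = 0,
                     referencePanel = data.frame(
                         gene = defaultPanel,
                         conditionSd = c(0, 0, 0, 1.2)))
    sim <- simulateCqDataset(cfg, seed = 21)
    expr <- normalizeCq(sim$cq, normParams(panel = defaultPanel))
    expr <- subtractOverlap(expr, "PI1", "KIN1")
    got <- meanQ(timeCourse(expr))["PI1", ]
    want <- trueProfiles(sim$truth)["PI1", names(got)]
    expect_equal(unname(got / want), rep(1, length(got)), tolerance = 1e-9)
})
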