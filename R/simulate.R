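# Synthetic-data generator: noise-free ground truth and the RT-qPCR
# forward model that turns it into quantification cycles.

# Temporal templates, evaluated on numeric stage values.  set1 declines
# exponentially from the floral transition; set2 rises logistically and
# collapses after pollination; set3 rises late and is still rising at the
# final stage; the pseudoset shares a broad early bump on a raised
# baseline.
groupTemplate <- function(group, s, p, resurgence = FALSE) {
    switch(group,
        set1 = {
            base <- 2^(-(s - s[1]) / p$halfLife)
            if (resurgence)
                base <- base + p$resurgenceHeight *
                    exp(-(s - p$resurgenceCenter)^2 / (2 * p$resurgenceWidth^2))
            base
        },
        set2 = plogis((s - p$onset) / p$width) *
            ifelse(s > p$dropAfter, p$dropFactor, 1),
        set3 = plogis((s - p$midpoint) / p$width),
        pseudoset = p$baseline + exp(-(s - p$center)^2 / (2 * p$width^2)),
        stop("no template for group ", group))
}

# Fixed per-member distortions for the pseudoset: directions orthogonal to
# the shared bump (and to each other), scaled so that the correlation
# between any two noise-free members equals the configured cohesion.  The
# Helmert basis makes the construction deterministic.
pseudosetProfiles <- function(n, s, p) {
    u <- groupTemplate("pseudoset", s, p)
    if (n == 1L) return(matrix(u, nrow = 1))
    H <- stats::contr.helmert(length(s))
    if (n > ncol(H)) stop("too many pseudoset genes for this stage grid")
    Q <- qr.Q(qr(cbind(u - mean(u), H)))[, seq_len(n) + 1L, drop = FALSE]
    a <- sd(u) * sqrt((1 - p$cohesion) / p$cohesion) * sqrt(length(s) - 1)
    t(vapply(seq_len(n), function(i) pmax(u + a * Q[, i], 0.02), u))
}

# Independent erratic profile, decorrelated from the pseudoset trend so
# that ungrouped genes act as true negatives for grouping.  Pearson r is
# shift-invariant, so re-shifting positive preserves the decorrelation.
erraticProfile <- function(s, logSd, trend) {
    x <- exp(rnorm(length(s), 0, logSd))
    tc <- trend - mean(trend)
    e <- x - sum(x * tc) / sum(tc * tc) * tc
    e - min(e) + 0.2
}

organExpectationWeights <- function(class, organs) {
    expected <- abcdeExpectation()[[class]]
    w <- setNames(rep(0, length(organs)), organs)
    if (is.null(expected)) w[] <- 0.3    # non-ABCDE genes: broad profile
    else w[expected] <- 1
    w
}

#' Generate noise-free ground truth for a synthetic study
#'
#' Draws per-gene noise-free expression profiles over the stage grid and
#' the floral organs.  Genes within \code{set1}/\code{set2}/\code{set3}
#' share their group template up to a per-gene positive scale and
#' multiplicative jitter bounded by \code{biologicalJitterSd}; pseudoset
#' genes share a broad early bump with fixed per-gene distortions and
#' larger jitter; ungrouped genes are mutually independent noise profiles.
#' Organ profiles follow the ABCDE expectation row of each gene's class
#' with multiplicative lognormal noise, plus any injected deviations.
#'
#' @param config A [simConfig()] object.
#' @param seed Integer seed; identical (config, seed) gives identical
#'   output.
#'
#' @return A [GroundTruth-class] object covering every target gene and
#'   reference candidate (references have flat unit profiles).
#' @export
#' @examples
#' truth <- generateTruth(simConfig(), seed = 1)
#' table(groupOf(truth))
generateTruth <- function(config, seed) {
    stopifnot(is(config, "SimConfig"))
    methods::validObject(config)
    set.seed(as.integer(seed))
    s <- config@stageGrid@values
    genes <- config@genes
    gp <- config@groupParams
    nS <- length(s)

    pseudoGenes <- genes$gene[genes$group == "pseudoset"]
    pseudoP <- pseudosetProfiles(max(length(pseudoGenes), 1L), s, gp$pseudoset)
    pseudoTrend <- groupTemplate("pseudoset", s, gp$pseudoset)

    profiles <- matrix(0, nrow(genes), nS,
                       dimnames = list(genes$gene, config@stageGrid@labels))
    organP <- matrix(0, nrow(genes), length(config@organs),
                     dimnames = list(genes$gene, config@organs))
    set1Seen <- 0L
    for (i in seq_len(nrow(genes))) {
        g <- genes$gene[i]; grp <- genes$group[i]
        scale <- genes$baseScale[i] * exp(rnorm(1, 0, config@scaleSd))
        prof <- switch(grp,
            set1 = {
                set1Seen <- set1Seen + 1L
                groupTemplate("set1", s, gp$set1,
                    resurgence = config@resurgenceEnabled && set1Seen == 1L) *
                    exp(rnorm(nS, 0, config@biologicalJitterSd))
            },
            set2 = ,
            set3 = groupTemplate(grp, s, gp[[grp]]) *
                exp(rnorm(nS, 0, config@biologicalJitterSd)),
            pseudoset = pseudoP[match(g, pseudoGenes), ] *
                exp(rnorm(nS, 0, config@pseudoJitterSd)),
            ungrouped = erraticProfile(s, gp$ungrouped$logSd, pseudoTrend))
        profiles[i, ] <- scale * prof

        w <- organExpectationWeights(genes$class[i], config@organs)
        dev <- config@organDeviations
        dev <- dev[dev$gene == g, , drop = FALSE]
        if (nrow(dev)) w[dev$organ] <- w[dev$organ] + dev$weight
        noise <- exp(rnorm(length(w), 0, config@organNoiseSd))
        organP[i, ] <- scale * w * noise
    }

    refs <- config@referencePanel$gene
    groupOf <- setNames(c(genes$group, rep("reference", length(refs))),
                        c(genes$gene, refs))
    profiles <- rbind(profiles,
        matrix(1, length(refs), nS,
               dimnames = list(refs, config@stageGrid@labels)))
    organP <- rbind(organP,
        matrix(1, length(refs), length(config@organs),
               dimnames = list(refs, config@organs)))

    methods::new("GroundTruth", groupOf = groupOf, profiles = profiles,
                 organProfiles = organP, stageGrid = config@stageGrid)
}

#' Forward-model ground truth into a raw Cq table
#'
#' Applies the RT-qPCR forward model: for expression \eqn{x > 0},
#' \eqn{Cq = baseCq - \log_2 x + \epsilon} with technical-replicate noise
#' \eqn{\epsilon \sim N(0, replicateSd)}; expression below the detection
#' floor (a fraction of the gene's maximum) is emitted as a missing Cq (no
#' amplification).  Reference candidates are generated flat at
#' \code{baseCq} plus their per-candidate between-condition noise.  For the
#' configured overlap pair, the target's assay measures target plus
#' background (the antisense transcript covers the target), while the
#' background assay measures the background alone.
#'
#' @param truth A [GroundTruth-class] from [generateTruth()].
#' @param config The matching [simConfig()].
#' @param seed Integer seed for the measurement noise.
#'
#' @return A [CqTable-class] covering all stage and organ conditions.
#' @export
#' @examples
#' cfg <- simConfig()
#' cq <- truthToCq(generateTruth(cfg, 1), cfg, seed = 2)
#' cq
truthToCq <- function(truth, config, seed) {
    stopifnot(is(truth, "GroundTruth"), is(config, "SimConfig"))
    set.seed(as.integer(seed))
    if (any(truth@profiles < 0) || any(truth@organProfiles < 0))
        stop("internal error: negative expression in ground truth")

    conds <- data.frame(
        condition = c(truth@stageGrid@labels, colnames(truth@organProfiles)),
        conditionType = rep(c("stage", "organ"),
                            c(length(truth@stageGrid@labels),
                              ncol(truth@organProfiles))),
        stringsAsFactors = FALSE)
    targets <- setdiff(names(groupOf(truth)),
                       config@referencePanel$gene)
    nRep <- config@nReplicates

    exprOf <- function(g, type) {
        if (type == "stage") truth@profiles[g, ] else truth@organProfiles[g, ]
    }
    rows <- vector("list", length(targets) + nrow(config@referencePanel))
    k <- 0L
    for (g in targets) {
        for (type in c("stage", "organ")) {
            x <- exprOf(g, type)
            if (length(config@overlapPair) &&
                g == config@overlapPair[["target"]])
                x <- x + exprOf(config@overlapPair[["background"]], type)
            floorAbs <- config@expressionFloor * max(x)
            cc <- conds$condition[conds$conditionType == type]
            cq <- matrix(NA_real_, length(cc), nRep)
            for (j in seq_along(cc)) {
                if (x[j] <= 0 || x[j] < floorAbs) next
                cq[j, ] <- config@baseCq - log2(x[j]) +
                    rnorm(nRep, 0, config@replicateSd)
            }
            k <- k + 1L
            rows[[k]] <- data.frame(gene = g, conditionType = type,
                condition = rep(cc, each = nRep),
                replicate = rep(seq_len(nRep), length(cc)),
                cq = as.vector(t(cq)), stringsAsFactors = FALSE)
        }
    }
    for (i in seq_len(nrow(config@referencePanel))) {
        ref <- config@referencePanel$gene[i]
        delta <- rnorm(nrow(conds), 0, config@referencePanel$conditionSd[i])
        cq <- config@baseCq + rep(delta, each = nRep) +
            rnorm(nrow(conds) * nRep, 0, config@replicateSd)
        k <- k + 1L
        rows[[k]] <- data.frame(gene = ref,
            conditionType = rep(conds$conditionType, each = nRep),
            condition = rep(conds$condition, each = nRep),
            replicate = rep(seq_len(nRep), nrow(conds)),
            cq = cq, stringsAsFactors = FALSE)
    }
    CqTable(records = do.call(rbind, rows[seq_len(k)]))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper drawing ground truth and its Cq-level measurement
#' from one seed (truth uses \code{seed}, the measurement layer
#' \code{seed + 1}).
#'
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#'
#' @return A list with elements \code{truth} ([GroundTruth-class]) and
#'   \code{cq} ([CqTable-class]).
#' @export
#' @examples
#' sim <- simulateCqDataset(simConfig(), seed = 42)
#' sim$cq
simulateCqDataset <- function(config, seed) {
    truth <- generateTruth(config, seed)
    list(truth = truth, cq = truthToCq(truth, config, as.integer(seed) + 1L))
}
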