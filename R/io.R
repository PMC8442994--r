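# Plain-text readers and writers for the pipeline's tables.

#' Read / write a Cq table
#'
#' The TSV dialect has columns \code{gene}, \code{condition_type}
#' (\code{stage}|\code{organ}), \code{condition}, \code{replicate} and
#' \code{cq}; an empty \code{cq} field records no amplification.
#'
#' @param path File path.
#' @return A [CqTable-class].
#' @export
readCqTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(cq = "numeric"))
    names(df)[names(df) == "condition_type"] <- "conditionType"
    CqTable(records = df)
}

#' @rdname readCqTable
#' @param x A [CqTable-class].
#' @export
writeCqTable <- function(x, path) {
    df <- cqRecords(x)
    names(df)[names(df) == "conditionType"] <- "condition_type"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' Read / write an expression matrix
#'
#' Long TSV with columns \code{gene}, \code{condition_type},
#' \code{condition}, \code{mean} and \code{sd}.
#'
#' @param path File path.
#' @return A [RelExpressionSet-class].
#' @export
readExpressionMatrix <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    genes <- unique(df$gene)
    conds <- unique(df[c("condition", "condition_type")])
    mk <- function(col) {
        m <- matrix(0, length(genes), nrow(conds),
                    dimnames = list(genes, conds$condition))
        m[cbind(match(df$gene, genes), match(df$condition, conds$condition))] <-
            df[[col]]
        m
    }
    sv <- ifelse(conds$condition_type == "stage",
                 suppressWarnings(as.numeric(sub("^W", "", conds$condition))),
                 NA_real_)
    RelExpressionSet(mk("mean"), mk("sd"), conds$condition_type, sv)
}

#' @rdname readExpressionMatrix
#' @param x A [RelExpressionSet-class].
#' @export
writeExpressionMatrix <- function(x, path) {
    m <- meanQ(x); s <- sdQ(x)
    df <- data.frame(
        gene = rep(rownames(m), ncol(m)),
        condition_type = rep(conditionType(x), each = nrow(m)),
        condition = rep(colnames(m), each = nrow(m)),
        mean = as.vector(m), sd = as.vector(s))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a correlation matrix as a square TSV
#'
#' @param corr Matrix from [pearsonMatrix()].
#' @param path File path.
#' @export
writeCorrelationMatrix <- function(corr, path) {
    write.table(data.frame(gene = rownames(corr), corr,
                           check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a set assignment as TSV
#'
#' Columns: \code{gene}, \code{label}, \code{n_partners},
#' \code{peak_stage}.
#'
#' @param x A [SetAssignment-class].
#' @param path File path.
#' @export
writeSetAssignment <- function(x, path) {
    df <- data.frame(gene = names(setLabels(x)), label = setLabels(x),
                     n_partners = x@nPartners, peak_stage = x@peakStage,
                     row.names = NULL)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Heatmap-ready log-scaled expression table
#'
#' Log10(Q + eps) values capped at a configurable upper quantile, the
#' transformation used to display expression spanning orders of magnitude
#' on a logarithmic colour scale with the maximum capped for contrast.
#'
#' @param expr A [RelExpressionSet-class].
#' @param eps Pseudocount (default 1e-3).
#' @param capQuantile Upper cap as a quantile of the transformed values
#'   (default 0.99).
#'
#' @return Numeric matrix of transformed, capped values.
#' @export
heatmapTable <- function(expr, eps = 1e-3, capQuantile = 0.99) {
    v <- log10(meanQ(expr) + eps)
    pmin(v, quantile(v, capQuantile))
}

#' Read / write a simulation configuration as YAML
#'
#' Serializes the tunable scalars, the gene roster, the reference panel
#' and the injected organ deviations; group template parameters and the
#' stage grid follow the defaults unless present in the file.
#'
#' @param path File path.
#' @return A [SimConfig-class].
#' @export
readSimConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for config files")
    y <- yaml::read_yaml(path)
    asDf <- function(x) if (is.null(x)) NULL else
        do.call(rbind.data.frame, c(x, stringsAsFactors = FALSE))
    args <- list(
        genes = asDf(y$genes),
        referencePanel = if (is.null(y$referencePanel))
            defaultReferencePanel() else asDf(y$referencePanel),
        organDeviations = if (is.null(y$organDeviations))
            data.frame(gene = character(0), organ = character(0),
                       weight = numeric(0)) else asDf(y$organDeviations),
        overlapPair = if (is.null(y$overlapPair)) character(0) else
            unlist(y$overlapPair))
    for (f in c("replicateSd", "biologicalJitterSd", "pseudoJitterSd",
                "scaleSd", "baseCq", "resurgenceEnabled",
                "expressionFloor", "organNoiseSd", "nReplicates"))
        if (!is.null(y[[f]])) args[[f]] <- y[[f]]
    do.call(simConfig, args)
}

#' @rdname readSimConfig
#' @param config A [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for config files")
    rowList <- function(df) lapply(seq_len(nrow(df)), function(i)
        as.list(df[i, , drop = FALSE]))
    yaml::write_yaml(list(
        genes = rowList(config@genes),
        referencePanel = rowList(config@referencePanel),
        organDeviations = rowList(config@organDeviations),
        overlapPair = as.list(config@overlapPair),
        replicateSd = config@replicateSd,
        biologicalJitterSd = config@biologicalJitterSd,
        pseudoJitterSd = config@pseudoJitterSd,
        scaleSd = config@scaleSd,
        baseCq = config@baseCq,
        resurgenceEnabled = config@resurgenceEnabled,
        expressionFloor = config@expressionFloor,
        organNoiseSd = config@organNoiseSd,
        nReplicates = config@nReplicates), path)
    invisible(path)
}

#' Write ground truth as TSV
#'
#' Writes the group labels and the noise-free stage profiles in one long
#' table: columns \code{gene}, \code{group}, then one column per stage.
#'
#' @param truth A [GroundTruth-class].
#' @param path File path.
#' @export
writeGroundTruth <- function(truth, path) {
    df <- data.frame(gene = names(groupOf(truth)), group = groupOf(truth),
                     trueProfiles(truth), row.names = NULL,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
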