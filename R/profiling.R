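# Developmental profile summaries and ABCDE-model conformance scoring.

# resolve a profile argument: a named numeric vector, or a gene row of a
# RelExpressionSet (stage or organ columns)
profileRows <- function(x, type) {
    if (is(x, "RelExpressionSet")) {
        sub <- if (type == "stage") timeCourse(x) else organPanel(x)
        meanQ(sub)
    } else if (is.numeric(x)) {
        matrix(x, nrow = 1, dimnames = list("profile", names(x)))
    } else stop("expected a RelExpressionSet or a named numeric profile")
}

#' Stage of peak expression
#'
#' The stage with maximum mean relative expression, ties broken by the
#' earliest stage.  All-zero profiles are reported as \code{"none"}.
#' Invariant under positive rescaling of the profile.
#'
#' @param x A [RelExpressionSet-class] (time-course columns are used) or a
#'   named numeric profile ordered by stage.
#'
#' @return Named character vector of stage labels.
#' @export
#' @examples
#' peakStage(c(W1 = 5, W2 = 2, W3 = 1))
peakStage <- function(x) {
    m <- profileRows(x, "stage")
    vapply(seq_len(nrow(m)), function(i) {
        if (all(m[i, ] == 0)) "none" else colnames(m)[which.max(m[i, ])]
    }, "") |> setNames(rownames(m))
}

#' Stage of expression onset
#'
#' The earliest stage where mean expression reaches a fraction \code{f} of
#' the profile maximum.  All-zero profiles are reported as \code{"none"}.
#' Non-decreasing in \code{f}; invariant under positive rescaling.
#'
#' @param x As in [peakStage()].
#' @param f Onset fraction in (0, 1); default 0.1.
#'
#' @return Named character vector of stage labels.
#' @export
#' @examples
#' onsetStage(c(W1 = 0, W2 = 0, W2.5 = 1, W3.5 = 8), f = 0.1)
onsetStage <- function(x, f = 0.1) {
    if (f <= 0 || f >= 1) stop("f must be in (0, 1)")
    m <- profileRows(x, "stage")
    vapply(seq_len(nrow(m)), function(i) {
        mx <- max(m[i, ])
        if (mx == 0) return("none")
        colnames(m)[which(m[i, ] >= f * mx)[1]]
    }, "") |> setNames(rownames(m))
}

#' Call the organs in which a gene is expressed
#'
#' Binarizes the organ panel: an organ is called expressed iff its mean
#' relative expression reaches \code{relThreshold} times the gene's maximum
#' over the organs.  All-zero rows give no calls.
#'
#' @param x A [RelExpressionSet-class] with the five floral-organ columns,
#'   or a named numeric organ profile.
#' @param relThreshold Fraction of the organ maximum (default 0.1).
#'
#' @return Logical genes-by-organs matrix.
#' @export
#' @examples
#' callExpressedOrgans(c(lemma = 10, palea = 9, lodicule = 0.1,
#'                       stamen = 0.1, carpel = 0.1))
callExpressedOrgans <- function(x, relThreshold = 0.1) {
    m <- profileRows(x, "organ")
    missing <- setdiff(floralOrgans(), colnames(m))
    if (length(missing))
        stop("missing organ column(s): ", paste(missing, collapse = ", "))
    m <- m[, floralOrgans(), drop = FALSE]
    mx <- apply(m, 1, max)
    calls <- m >= relThreshold * mx
    calls[mx == 0, ] <- FALSE
    calls
}

#' ABCDE organ-expression expectations
#'
#' The organ subsets in which each gene class is expected to be expressed,
#' following the whorl logic of the ABCDE model on grass floral organs
#' (lemma/palea = whorl 1, lodicule = whorl 2, stamen = whorl 3, carpel =
#' whorl 4): A acts in whorls 1-2, B in 2-3, C in 3-4, D in the ovule
#' (carpel sample), E in all whorls.  By default the E class is split into
#' its two SEPALLATA subclades, LOFSEP expected in the outer organs and
#' SEP3 in the inner organs; \code{splitE = FALSE} restores the classic
#' undivided E expectation.
#'
#' @param splitE Split the E class into E-LOFSEP and E-SEP3 (default
#'   \code{TRUE}).
#'
#' @return Named list: class label to expected organ subset.
#' @export
#' @examples
#' abcdeExpectation()$B
abcdeExpectation <- function(splitE = TRUE) {
    base <- list(
        A = c("lemma", "palea", "lodicule"),
        B = c("lodicule", "stamen"),
        C = c("stamen", "carpel"),
        D = "carpel")
    if (splitE)
        c(base, list(`E-LOFSEP` = c("lemma", "palea"),
                     `E-SEP3` = c("lodicule", "stamen", "carpel")))
    else
        c(base, list(E = c("lemma", "palea", "lodicule", "stamen", "carpel")))
}

#' Score organ calls against ABCDE expectations
#'
#' Per gene, compares the called organ set with the expectation for its
#' class: \code{unexpected} organs are called but not expected,
#' \code{absent} organs are expected but not called; the verdict is
#' \code{conforming} iff both are empty, and depends only on the call sets,
#' never on expression magnitude.  Genes of class \code{"other"} (outside
#' the ABCDE model) are reported descriptively with verdict \code{"n/a"}.
#'
#' @param calls Logical genes-by-organs matrix from
#'   [callExpressedOrgans()], or a named list of called organ subsets.
#' @param classMap Named character vector: gene to class (\code{"A"},
#'   \code{"B"}, \code{"C"}, \code{"D"}, \code{"E-LOFSEP"},
#'   \code{"E-SEP3"}, \code{"E"} or \code{"other"}).
#' @param expectation From [abcdeExpectation()].
#'
#' @return data.frame with columns \code{gene}, \code{class},
#'   \code{called}, \code{expected}, \code{unexpected}, \code{absent}
#'   (comma-separated organ lists) and \code{verdict}.
#' @export
#' @examples
#' calls <- callExpressedOrgans(c(lemma = 0, palea = 0, lodicule = 5,
#'                                stamen = 6, carpel = 0.01))
#' rownames(calls) <- "PI1"
#' classifyABCDE(calls, c(PI1 = "B"))
classifyABCDE <- function(calls, classMap,
                          expectation = abcdeExpectation()) {
    if (is.matrix(calls)) {
        calls <- apply(calls, 1, function(r) colnames(calls)[r],
                       simplify = FALSE)
    }
    badOrgan <- setdiff(unique(unlist(c(calls, expectation))), floralOrgans())
    if (length(badOrgan))
        stop("unknown organ name(s): ", paste(badOrgan, collapse = ", "))
    genes <- names(calls)
    res <- lapply(genes, function(g) {
        cls <- if (g %in% names(classMap)) classMap[[g]] else "other"
        called <- calls[[g]]
        if (cls == "other" || !cls %in% names(expectation)) {
            return(data.frame(gene = g, class = cls,
                called = paste(called, collapse = ","), expected = "",
                unexpected = "", absent = "", verdict = "n/a",
                stringsAsFactors = FALSE))
        }
        exp_ <- expectation[[cls]]
        unexp <- setdiff(called, exp_)
        absent <- setdiff(exp_, called)
        data.frame(gene = g, class = cls,
            called = paste(called, collapse = ","),
            expected = paste(exp_, collapse = ","),
            unexpected = paste(unexp, collapse = ","),
            absent = paste(absent, collapse = ","),
            verdict = if (!length(unexp) && !length(absent)) "conforming"
                      else "deviating",
            stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Per-gene profile and conformance report
#'
#' Combines the timing summaries (peak and onset stage) with the organ
#' calls and the ABCDE verdict into one per-gene table.
#'
#' @param expr A [RelExpressionSet-class] with both stage and organ
#'   columns.
#' @param classMap Named character vector: gene to ABCDE class.
#' @param f Onset fraction (see [onsetStage()]).
#' @param relThreshold Organ call threshold (see [callExpressedOrgans()]).
#' @param expectation From [abcdeExpectation()].
#'
#' @return data.frame with one row per gene.
#' @export
profileReport <- function(expr, classMap, f = 0.1, relThreshold = 0.1,
                          expectation = abcdeExpectation()) {
    conf <- classifyABCDE(callExpressedOrgans(expr, relThreshold),
                          classMap, expectation)
    data.frame(gene = conf$gene, class = conf$class,
        peak_stage = peakStage(expr)[conf$gene],
        onset_stage = onsetStage(expr, f)[conf$gene],
        organs_called = conf$called, verdict = conf$verdict,
        unexpected = conf$unexpected, absent = conf$absent,
        row.names = NULL, stringsAsFactors = FALSE)
}
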