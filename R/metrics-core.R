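#' @include panel-internal.R
NULL

#' Basic confusion-matrix rates
#'
#' Computes the four basic rates and their complements from a confusion
#' matrix: true positive rate `TPR = TP/(TP+FN)` (sensitivity, recall),
#' true negative rate `TNR = TN/(TN+FP)` (specificity), positive predictive
#' value `PPV = TP/(TP+FP)` (precision), negative predictive value
#' `NPV = TN/(TN+FN)`, and `FNR = 1-TPR`, `FPR = 1-TNR`, `FDR = 1-PPV`,
#' `FOR = 1-NPV`. A rate whose denominator is zero is undefined (`NA`):
#' `x/(x+y)` has no limit at the origin, so no substitute value exists.
#' Complements are undefined exactly when their base rate is.
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return Named numeric vector
#'   `c(tpr, tnr, ppv, npv, fdr, fnr, fpr, for)`; `NA` = undefined.
#' @examples
#' basicRates(ConfusionMatrix(tp = 100, fn = 1, fp = 5000, tn = 94900))
#' @rdname basicRates
#' @export
setMethod("basicRates", "CMTable", function(x) {
    .panelOf(x)[c("tpr", "tnr", "ppv", "npv", "fdr", "fnr", "fpr", "for")]
})

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' Pearson correlation between the reference and predicted binary labels.
#' Range `[-1, 1]`; 0 for a classifier uncorrelated with the truth.
#'
#' The raw formula is 0/0 whenever a row or column of the matrix is empty.
#' This implementation uses the total zero-extension: any matrix with a
#' vanishing marginal gets MCC = 0, so MCC is defined for every confusion
#' matrix (unlike BA, BM and MK, which are genuinely undefined there).
#' The perfect-degenerate matrices (`tp == N` or `tn == N`) also map to 0;
#' [metricPanel()] flags them with a degeneracy note.
#'
#' @param x a [ConfusionMatrix-class], [RelativeConfusionMatrix-class] or
#'   [MetricPanel-class].
#' @return A single number in `[-1, 1]`; never `NA`.
#' @examples
#' mcc(ConfusionMatrix(100, 1, 5000, 94900))   # 0.136
#' mcc(ConfusionMatrix(25, 25, 25, 25))        # 0
#' @rdname mcc
#' @export
setMethod("mcc", "CMTable", function(x) {
    unname(.mccVec(x@tp, x@fn, x@fp, x@tn, .zeroTolOf(x)))
})

#' Balanced accuracy, bookmaker informedness and markedness
#'
#' `BA = (TPR+TNR)/2`, `BM = TPR+TNR-1` (bookmaker informedness, identical
#' to Youden's J and Peirce's I) and `MK = PPV+NPV-1` (markedness). BA and
#' BM carry the same information (`BA = (BM+1)/2`); both describe the
#' classifier independently of prevalence, while MK is their
#' predictive-value counterpart. BA and BM are undefined (`NA`) when
#' `(TP+FN)*(TN+FP) = 0`; MK when `(TP+FP)*(TN+FN) = 0`.
#'
#' @param x a [ConfusionMatrix-class], [RelativeConfusionMatrix-class] or
#'   [MetricPanel-class].
#' @return A single number (`NA` = undefined); BA in `[0, 1]`, BM and MK
#'   in `[-1, 1]`.
#' @examples
#' cm2 <- ConfusionMatrix(90000, 10000, 1, 9)
#' balancedAccuracy(cm2)  # 0.9
#' bookmaker(cm2)         # 0.8
#' markedness(cm2)        # 0.001
#' @name multiCategoryMetrics
#' @rdname multiCategoryMetrics
NULL

#' @rdname multiCategoryMetrics
#' @export
setMethod("balancedAccuracy", "CMTable",
          function(x) unname(.panelOf(x)["ba"]))

#' @rdname multiCategoryMetrics
#' @export
setMethod("bookmaker", "CMTable", function(x) unname(.panelOf(x)["bm"]))

#' @rdname multiCategoryMetrics
#' @export
setMethod("markedness", "CMTable", function(x) unname(.panelOf(x)["mk"]))

#' Accuracy and F1 score
#'
#' `accuracy = (TP+TN)/N`, algebraically equal to
#' `TPR*phi + TNR*(1-phi)`; `F1 = 2*PPV*TPR/(PPV+TPR)`, the harmonic mean
#' of precision and recall. F1 is undefined when PPV or TPR is undefined,
#' or when `PPV + TPR = 0`.
#'
#' @param x a [ConfusionMatrix-class], [RelativeConfusionMatrix-class] or
#'   [MetricPanel-class].
#' @return A single number in `[0, 1]` (`NA` = undefined for F1).
#' @examples
#' accuracy(ConfusionMatrix(50, 0, 0, 50))  # 1
#' f1Score(ConfusionMatrix(50, 0, 0, 50))   # 1
#' @name accuracyF1
#' @rdname accuracyF1
NULL

#' @rdname accuracyF1
#' @export
setMethod("accuracy", "CMTable", function(x) unname(.panelOf(x)["accuracy"]))

#' @rdname accuracyF1
#' @export
setMethod("f1Score", "CMTable", function(x) unname(.panelOf(x)["f1"]))

#' Full metric panel of a confusion matrix
#'
#' Computes all fourteen metrics (eight basic rates, MCC, BA, BM, MK,
#' accuracy, F1) in one consistent pass and records degeneracy notes for
#' matrices with empty rows/columns (including the perfect-degenerate
#' `tp == N` / `tn == N` cases, where the zero-extended MCC is 0 despite a
#' perfect classification).
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return A [MetricPanel-class] object.
#' @examples
#' metricPanel(ConfusionMatrix(100, 1, 5000, 94900))
#' @rdname metricPanel
#' @export
setMethod("metricPanel", "CMTable", function(x) {
    v <- .panelOf(x)
    zt <- .zeroTolOf(x)
    notes <- character()
    n <- cmN(x)
    if (x@tp + x@fn <= zt) notes <- c(notes, "no reference positives")
    if (x@tn + x@fp <= zt) notes <- c(notes, "no reference negatives")
    if (x@tp + x@fp <= zt) notes <- c(notes, "no positive predictions")
    if (x@tn + x@fn <= zt) notes <- c(notes, "no negative predictions")
    if (x@tp >= n - zt || x@tn >= n - zt)
        notes <- c(notes,
                   "perfect-degenerate matrix: zero-extended MCC is 0")
    new("MetricPanel", values = v, notes = notes)
})

## Panel accessors: the metric generics also extract from a computed panel.
#' @rdname mcc
#' @export
setMethod("mcc", "MetricPanel", function(x) unname(x@values["mcc"]))
#' @rdname multiCategoryMetrics
#' @export
setMethod("balancedAccuracy", "MetricPanel",
          function(x) unname(x@values["ba"]))
#' @rdname multiCategoryMetrics
#' @export
setMethod("bookmaker", "MetricPanel", function(x) unname(x@values["bm"]))
#' @rdname multiCategoryMetrics
#' @export
setMethod("markedness", "MetricPanel", function(x) unname(x@values["mk"]))
#' @rdname accuracyF1
#' @export
setMethod("accuracy", "MetricPanel",
          function(x) unname(x@values["accuracy"]))
#' @rdname accuracyF1
#' @export
setMethod("f1Score", "MetricPanel", function(x) unname(x@values["f1"]))
#' @rdname basicRates
#' @export
setMethod("basicRates", "MetricPanel", function(x)
    x@values[c("tpr", "tnr", "ppv", "npv", "fdr", "fnr", "fpr", "for")])

#' Degeneracy notes of a metric panel
#'
#' @param panel a [MetricPanel-class].
#' @return Character vector of notes (empty for non-degenerate matrices).
#' @export
panelNotes <- function(panel) {
    stopifnot(is(panel, "MetricPanel"))
    panel@notes
}

#' Swap the class labels of a confusion matrix
#'
#' Exchanges the roles of the positive and negative class:
#' `tp <-> tn`, `fn <-> fp`. MCC, BA, BM and MK are invariant under this
#' swap (where defined); the F1 score generally is not. Applying the swap
#' twice returns the original matrix.
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return An object of the same class with labels swapped.
#' @examples
#' swapLabels(ConfusionMatrix(90000, 10000, 1, 9))
#' @rdname swapLabels
#' @export
setMethod("swapLabels", "CMTable", function(x) {
    initialize(x, tp = x@tn, fn = x@fp, fp = x@fn, tn = x@tp)
})

#' Build a confusion matrix from paired label vectors
#'
#' Tabulates reference and predicted binary labels into a
#' [ConfusionMatrix-class]. The positive class is coded as 1
#' (or `TRUE`); any two-valued coding works via `positive=`.
#'
#' @param reference,predicted equal-length vectors of binary labels
#'   (logical, 0/1 numeric, or any type when `positive` is given).
#' @param positive the value denoting the positive class; default `1`
#'   (works for logical and 0/1 input).
#' @return A [ConfusionMatrix-class].
#' @examples
#' cmFromLabels(c(1, 1, 0), c(1, 0, 0))  # tp=1 fn=1 fp=0 tn=1
#' @export
cmFromLabels <- function(reference, predicted, positive = 1) {
    if (length(reference) != length(predicted))
        stop("reference and predicted must have equal length")
    if (length(reference) < 1L)
        stop("label vectors must have length >= 1")
    ref <- reference == positive
    prd <- predicted == positive
    if (anyNA(ref) || anyNA(prd))
        stop("labels must not contain NA")
    if (length(unique(reference[!ref])) > 1L ||
        length(unique(predicted[!prd])) > 1L)
        stop("labels must be binary (one positive and one negative value)")
    ConfusionMatrix(tp = sum(ref & prd), fn = sum(ref & !prd),
                    fp = sum(!ref & prd), tn = sum(!ref & !prd))
}
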