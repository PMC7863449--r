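#' @import methods
NULL

## Denominators of the basic rates are compared to zero exactly for count
## matrices and to < 1e-12 for relative matrices (shares are doubles).
.REL_TOL <- 1e-12

#' Virtual parent of count and relative confusion matrices
#'
#' Both representations store the four cells of a 2x2 confusion matrix:
#' true positives, false negatives, false positives and true negatives.
#' `ConfusionMatrix` holds non-negative integer counts; [RelativeConfusionMatrix]
#' holds shares summing to one. All metric generics accept either.
#'
#' @slot tp,fn,fp,tn single non-negative numbers.
#'
#' @aliases CMTable-class
#' @exportClass CMTable
setClass("CMTable",
         representation("VIRTUAL",
                        tp = "numeric", fn = "numeric",
                        fp = "numeric", tn = "numeric"))

.validCells <- function(object) {
    v <- c(object@tp, object@fn, object@fp, object@tn)
    if (length(v) != 4L || anyNA(v) || any(!is.finite(v)))
        return("tp, fn, fp, tn must each be a single finite number")
    if (any(v < 0))
        return("confusion-matrix cells must be non-negative")
    TRUE
}

#' Two-class confusion matrix of counts
#'
#' @slot tp,fn,fp,tn non-negative integer counts; their sum (the sample
#'   size N) must be at least 1.
#'
#' @seealso [ConfusionMatrix()] for the constructor, [metricPanel()],
#'   [swapLabels()], [prevalence()], [bias()].
#' @aliases ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix", contains = "CMTable",
         validity = function(object) {
             ok <- .validCells(object)
             if (!isTRUE(ok)) return(ok)
             v <- c(object@tp, object@fn, object@fp, object@tn)
             if (any(abs(v - round(v)) > 1e-9))
                 return("counts must be integer-valued")
             if (sum(v) < 1)
                 return("total sample size N must be >= 1")
             TRUE
         })

#' Relative (share-based) two-class confusion matrix
#'
#' Stores the shares of the four categories rather than counts; the shares
#' must sum to 1. This removes the sample-size dependence and is the form
#' used when comparing metrics across sample sizes.
#'
#' @slot tp,fn,fp,tn shares in `[0, 1]` summing to 1 (tolerance 1e-9).
#'
#' @seealso [RelativeConfusionMatrix()], [relativeForm()], [cmFromRates()].
#' @aliases RelativeConfusionMatrix-class
#' @exportClass RelativeConfusionMatrix
setClass("RelativeConfusionMatrix", contains = "CMTable",
         validity = function(object) {
             ok <- .validCells(object)
             if (!isTRUE(ok)) return(ok)
             s <- object@tp + object@fn + object@fp + object@tn
             if (abs(s - 1) > 1e-9)
                 return(sprintf("shares must sum to 1 (got %.12g)", s))
             TRUE
         })

#' Rate-space parameterization of a confusion matrix
#'
#' A confusion matrix is equivalently described by the sample size N, the
#' prevalence phi (share of reference positives), the true positive rate and
#' the true negative rate: TP = N*TPR*phi, FN = N*(1-TPR)*phi,
#' TN = N*TNR*(1-phi), FP = N*(1-TNR)*(1-phi). The mapping is lossless
#' whenever both reference classes are present. When `phi` is 0 or 1 the
#' rate of the absent class carries no information and is not identifiable
#' from the matrix.
#'
#' @slot n positive sample size.
#' @slot phi prevalence in `[0, 1]`.
#' @slot tpr,tnr class-conditional rates in `[0, 1]`; `NA` allowed for the
#'   rate of an absent class (non-identifiable).
#'
#' @seealso [rateParameterization()], [cmFromRates()].
#' @aliases RateParameterization-class
#' @exportClass RateParameterization
setClass("RateParameterization",
         representation(n = "numeric", phi = "numeric",
                        tpr = "numeric", tnr = "numeric"),
         validity = function(object) {
             if (length(object@n) != 1L || is.na(object@n) || object@n < 1)
                 return("n must be a single number >= 1")
             for (nm in c("phi", "tpr", "tnr")) {
                 x <- slot(object, nm)
                 if (length(x) != 1L)
                     return(sprintf("%s must be a single number", nm))
                 if (!is.na(x) && (x < -1e-12 || x > 1 + 1e-12))
                     return(sprintf("%s must lie in [0, 1]", nm))
             }
             if (is.na(object@phi))
                 return("phi must not be NA")
             TRUE
         })

## Canonical metric order; "for" is the false omission rate.
.PANEL_METRICS <- c("tpr", "tnr", "ppv", "npv", "fdr", "fnr", "fpr", "for",
                    "mcc", "ba", "bm", "mk", "accuracy", "f1")

#' Panel of all confusion-matrix metrics for one matrix
#'
#' Holds the eight basic rates (TPR, TNR, PPV, NPV and their complements
#' FNR, FPR, FDR, FOR), the multi-category metrics MCC, BA, BM, MK, plus
#' accuracy and the F1 score, computed from a single confusion matrix.
#' A metric whose defining denominator vanishes is stored as `NA` (the
#' undefined marker, see [isUndefined()]); MCC uses the total
#' zero-extension and is always defined.
#'
#' @slot values named numeric vector over the fixed metric set; `NA` marks
#'   an undefined metric.
#' @slot notes character vector of degeneracy notes (empty when the matrix
#'   has all four marginals positive).
#'
#' @seealso [metricPanel()], [as.data.frame,MetricPanel-method]
#' @aliases MetricPanel-class
#' @exportClass MetricPanel
setClass("MetricPanel",
         representation(values = "numeric", notes = "character"),
         validity = function(object) {
             if (!identical(names(object@values), .PANEL_METRICS))
                 return("values must be named exactly by the fixed metric set")
             v <- object@values
             unit <- c("tpr", "tnr", "ppv", "npv", "fdr", "fnr", "fpr", "for",
                       "ba", "accuracy", "f1")
             if (any(v[unit] < -1e-9 | v[unit] > 1 + 1e-9, na.rm = TRUE))
                 return("rates, BA, accuracy and F1 must lie in [0, 1]")
             signed <- c("mcc", "bm", "mk")
             if (any(abs(v[signed]) > 1 + 1e-9, na.rm = TRUE))
                 return("MCC, BM and MK must lie in [-1, 1]")
             TRUE
         })

## ---- constructors -------------------------------------------------------

#' Construct a confusion matrix of counts
#'
#' @param tp,fn,fp,tn non-negative integer counts of true positives, false
#'   negatives, false positives and true negatives.
#' @return A [ConfusionMatrix-class] object.
#' @examples
#' cm <- ConfusionMatrix(tp = 100, fn = 1, fp = 5000, tn = 94900)
#' mcc(cm)
#' @export
ConfusionMatrix <- function(tp, fn, fp, tn) {
    new("ConfusionMatrix", tp = as.numeric(tp), fn = as.numeric(fn),
        fp = as.numeric(fp), tn = as.numeric(tn))
}

#' Construct a relative confusion matrix of shares
#'
#' @param tp,fn,fp,tn shares in `[0, 1]`; must sum to 1.
#' @return A [RelativeConfusionMatrix-class] object.
#' @examples
#' RelativeConfusionMatrix(0.35, 0.15, 0.15, 0.35)
#' @export
RelativeConfusionMatrix <- function(tp, fn, fp, tn) {
    new("RelativeConfusionMatrix", tp = as.numeric(tp), fn = as.numeric(fn),
        fp = as.numeric(fp), tn = as.numeric(tn))
}

#' Construct a rate-space parameterization
#'
#' @param n sample size (>= 1).
#' @param phi prevalence of the positive class in `[0, 1]`.
#' @param tpr,tnr true positive and true negative rate in `[0, 1]`; `NA`
#'   marks the non-identifiable rate of a class absent from the data.
#' @return A [RateParameterization-class] object.
#' @examples
#' rateParameterization(n = 200, phi = 0.5, tpr = 0.7, tnr = 0.7)
#' @export
rateParameterization <- function(n, phi, tpr, tnr) {
    new("RateParameterization", n = as.numeric(n), phi = as.numeric(phi),
        tpr = as.numeric(tpr), tnr = as.numeric(tnr))
}

## ---- basic accessors ----------------------------------------------------

#' Cell counts / shares of a confusion matrix
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return Named numeric vector `c(tp, fn, fp, tn)`.
#' @export
cmCounts <- function(x) {
    stopifnot(is(x, "CMTable"))
    c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn)
}

#' Total sample size of a confusion matrix
#'
#' @param x a [ConfusionMatrix-class] (for a relative matrix the total is 1).
#' @return The sum of the four cells.
#' @export
cmN <- function(x) {
    stopifnot(is(x, "CMTable"))
    x@tp + x@fn + x@fp + x@tn
}

#' Test for the undefined metric marker
#'
#' Metrics whose defining denominator vanishes (e.g. TPR of a matrix with
#' no reference positives) have no meaningful value: no limit of x/(x+y)
#' exists at the origin, so no number can stand in for them. They are
#' represented as `NA` and serialized as the literal `"undefined"`.
#'
#' @param x numeric vector (e.g. a metric value or panel values).
#' @return Logical vector, `TRUE` where the value is undefined.
#' @examples
#' isUndefined(basicRates(ConfusionMatrix(0, 0, 3, 7))["tpr"])
#' @export
isUndefined <- function(x) is.na(x)

## ---- show methods -------------------------------------------------------

## table layout: rows = reference class, cols = predicted class
.fmtCells <- function(x, digits = 6) {
    m <- matrix(c(x@tp, x@fn, x@fp, x@tn), 2, 2, byrow = TRUE,
                dimnames = list(c("ref +", "ref -"), c("pred +", "pred -")))
    print(signif(m, digits))
}

setMethod("show", "ConfusionMatrix", function(object) {
    cat(sprintf("ConfusionMatrix (N = %s)\n",
                format(cmN(object), big.mark = ",")))
    .fmtCells(object, digits = 12)
})

setMethod("show", "RelativeConfusionMatrix", function(object) {
    cat("RelativeConfusionMatrix (shares sum to 1)\n")
    .fmtCells(object)
})

setMethod("show", "RateParameterization", function(object) {
    cat(sprintf(
        "RateParameterization: N = %s, phi = %.6g, TPR = %s, TNR = %s\n",
        format(object@n, big.mark = ","), object@phi,
        ifelse(is.na(object@tpr), "undefined", sprintf("%.6g", object@tpr)),
        ifelse(is.na(object@tnr), "undefined", sprintf("%.6g", object@tnr))))
})

setMethod("show", "MetricPanel", function(object) {
    cat("MetricPanel\n")
    v <- object@values
    lab <- toupper(names(v))
    lab[lab == "ACCURACY"] <- "Accuracy"
    lab[lab == "F1"] <- "F1"
    out <- ifelse(is.na(v), "undefined", sprintf("% .3f", v))
    for (i in seq_along(v))
        cat(sprintf("  %-9s %s\n", lab[i], out[i]))
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' Coerce a metric panel to a one-row data frame
#'
#' @param x a [MetricPanel-class].
#' @param row.names,optional,... passed through for S3/S4 compatibility;
#'   unused.
#' @return A one-row `data.frame` with one column per metric (`NA` for
#'   undefined values).
#' @export
setMethod("as.data.frame", "MetricPanel",
          function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(as.list(x@values), row.names = row.names,
                  check.names = FALSE)
})
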