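#' @include metrics-core.R
NULL

#' Prevalence and bias of a confusion matrix
#'
#' Prevalence `phi = (TP+FN)/N` is the share of reference positives in the
#' dataset and is intrinsic to the data. Bias `beta = (TP+FP)/N` is the
#' share of positive predictions and depends on both data and classifier;
#' it equals `TPR*phi + (1-TNR)*(1-phi)` whenever TPR and TNR are defined.
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return A single number in `[0, 1]`.
#' @examples
#' cm <- ConfusionMatrix(8, 2, 38, 152)   # Table 2 classifier B
#' prevalence(cm)  # 0.05
#' bias(cm)        # 0.23
#' @name prevalenceBias
#' @rdname prevalenceBias
NULL

#' @rdname prevalenceBias
#' @export
setMethod("prevalence", "CMTable",
          function(x) (x@tp + x@fn) / cmN(x))

#' @rdname prevalenceBias
#' @export
setMethod("bias", "CMTable",
          function(x) (x@tp + x@fp) / cmN(x))

#' Rate-space coordinates of a confusion matrix
#'
#' Extracts the lossless alternative coordinates `(N, phi, TPR, TNR)`.
#' When a reference class is absent its rate is non-identifiable and
#' returned as `NA`.
#'
#' @param x a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class]
#'   (for a relative matrix, `n` is 1).
#' @return A [RateParameterization-class].
#' @examples
#' rateParam(ConfusionMatrix(100, 1, 5000, 94900))
#' @rdname rateParam
#' @export
setMethod("rateParam", "CMTable", function(x) {
    r <- basicRates(x)
    rateParameterization(n = cmN(x), phi = prevalence(x),
                         tpr = r[["tpr"]], tnr = r[["tnr"]])
})

#' Confusion matrix from rate-space coordinates
#'
#' Inverts the reparameterization: the shares are
#' `tp = TPR*phi`, `fn = (1-TPR)*phi`, `fp = (1-TNR)*(1-phi)`,
#' `tn = TNR*(1-phi)` and sum to 1 exactly. With `output = "counts"` the
#' shares are scaled by N and rounded by the largest-remainder method,
#' which preserves the total N; a warning is emitted when any cell moves
#' by 0.5 or more (the requested rates are then not exactly representable
#' at this N).
#'
#' @param p a [RateParameterization-class] (an `NA` rate of an absent
#'   class is treated as 0 for the vanishing products).
#' @param output `"relative"` (default) or `"counts"`.
#' @return A [RelativeConfusionMatrix-class] or [ConfusionMatrix-class].
#' @examples
#' p <- rateParameterization(100001, 101 / 100001, 100 / 101, 94900 / 99900)
#' cmFromRates(p, output = "counts")   # TP=100 FN=1 FP=5000 TN=94900
#' @export
cmFromRates <- function(p, output = c("relative", "counts")) {
    stopifnot(is(p, "RateParameterization"))
    output <- match.arg(output)
    tpr <- p@tpr; tnr <- p@tnr; phi <- p@phi
    ## rate of an absent class multiplies a zero share
    if (is.na(tpr)) { if (phi > 0) stop("tpr is NA but phi > 0"); tpr <- 0 }
    if (is.na(tnr)) { if (phi < 1) stop("tnr is NA but phi < 1"); tnr <- 0 }
    sh <- c(tp = tpr * phi, fn = (1 - tpr) * phi,
            fp = (1 - tnr) * (1 - phi), tn = tnr * (1 - phi))
    sh <- sh / sum(sh)  # guard against last-bit drift; sum is 1 analytically
    if (output == "relative")
        return(RelativeConfusionMatrix(sh["tp"], sh["fn"], sh["fp"], sh["tn"]))
    cnt <- .largestRemainder(sh * p@n, p@n)
    if (max(abs(cnt - sh * p@n)) >= 0.5)
        warning("rounding moved a cell by >= 0.5; ",
                "the rates are not exactly representable at this N")
    ConfusionMatrix(cnt["tp"], cnt["fn"], cnt["fp"], cnt["tn"])
}

## Largest-remainder rounding of non-negative reals to integers with a
## fixed total; ties broken by position (tp, fn, fp, tn).
.largestRemainder <- function(x, total) {
    fl <- floor(x)
    rem <- as.integer(round(total - sum(fl)))
    if (rem > 0) {
        ord <- order(x - fl, decreasing = TRUE)
        fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
    }
    fl
}

#' Predictive values from prevalence and the class-conditional rates
#'
#' Bayes' rule in rate space:
#' `PPV = TPR*phi / (TPR*phi + (1-TNR)*(1-phi))` and
#' `NPV = TNR*(1-phi) / ((1-TPR)*phi + TNR*(1-phi))`. These make the
#' prevalence-dependence of precision and NPV explicit: a test with high
#' TPR and TNR can still have tiny PPV at low prevalence.
#'
#' @param tpr,tnr,phi numbers in `[0, 1]`.
#' @return A single number in `[0, 1]`, or `NA` (undefined) when the
#'   denominator vanishes.
#' @examples
#' ppvFromRates(0.99, 0.95, 0.001)  # ~0.019: screening at low prevalence
#' npvFromRates(0.99, 0.95, 0.001)  # ~0.99999
#' @name predictiveFromRates
#' @rdname predictiveFromRates
NULL

.checkUnit <- function(...) {
    v <- c(...)
    if (anyNA(v) || any(v < 0 | v > 1))
        stop("rate arguments must lie in [0, 1]")
}

#' @rdname predictiveFromRates
#' @export
ppvFromRates <- function(tpr, tnr, phi) {
    .checkUnit(tpr, tnr, phi)
    den <- tpr * phi + (1 - tnr) * (1 - phi)
    if (den == 0) NA_real_ else tpr * phi / den
}

#' @rdname predictiveFromRates
#' @export
npvFromRates <- function(tpr, tnr, phi) {
    .checkUnit(tpr, tnr, phi)
    den <- (1 - tpr) * phi + tnr * (1 - phi)
    if (den == 0) NA_real_ else tnr * (1 - phi) / den
}

#' Class-conditional rates from the predictive values and bias
#'
#' The inverse direction of Bayes' rule:
#' `TPR = PPV*beta / (PPV*beta + (1-NPV)*(1-beta))` and
#' `TNR = NPV*(1-beta) / ((1-PPV)*beta + NPV*(1-beta))`. Composed with
#' [ppvFromRates()]/[npvFromRates()] and `beta = TPR*phi + (1-TNR)(1-phi)`
#' this recovers the original `(TPR, TNR)` on non-degenerate matrices.
#'
#' @param ppv,npv,beta numbers in `[0, 1]`.
#' @return A single number in `[0, 1]`, or `NA` when the denominator
#'   vanishes.
#' @examples
#' tprFromPredictive(0.7, 0.7, 0.5)  # 0.7 by symmetry
#' @name ratesFromPredictive
#' @rdname ratesFromPredictive
NULL

#' @rdname ratesFromPredictive
#' @export
tprFromPredictive <- function(ppv, npv, beta) {
    .checkUnit(ppv, npv, beta)
    den <- ppv * beta + (1 - npv) * (1 - beta)
    if (den == 0) NA_real_ else ppv * beta / den
}

#' @rdname ratesFromPredictive
#' @export
tnrFromPredictive <- function(ppv, npv, beta) {
    .checkUnit(ppv, npv, beta)
    den <- (1 - ppv) * beta + npv * (1 - beta)
    if (den == 0) NA_real_ else npv * (1 - beta) / den
}

#' Relative form of a count confusion matrix
#'
#' Divides each cell by the total N, giving the share-based representation.
#'
#' @param x a [ConfusionMatrix-class] (a relative matrix is returned
#'   unchanged).
#' @return A [RelativeConfusionMatrix-class].
#' @examples
#' relativeForm(ConfusionMatrix(70, 30, 30, 70))
#' @rdname relativeForm
#' @export
setMethod("relativeForm", "CMTable", function(x) {
    n <- cmN(x)
    RelativeConfusionMatrix(x@tp / n, x@fn / n, x@fp / n, x@tn / n)
})
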