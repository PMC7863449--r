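#' @include reparam.R
NULL

## All identities are smooth rational/radical functions of the counts, so
## an absolute tolerance of 1e-10 on metrics in [-1, 1] is comfortably
## within double precision.
.IDENTITY_TOL <- 1e-10

#' Balanced accuracy from bookmaker informedness
#'
#' `BA = (BM + 1)/2`: the two metrics are affinely linked and carry the
#' same information. `NA` (undefined) propagates.
#'
#' @param bm bookmaker informedness in `[-1, 1]` or `NA`.
#' @return Balanced accuracy in `[0, 1]` or `NA`.
#' @examples
#' baFromBM(0.8)  # 0.9
#' @export
baFromBM <- function(bm) {
    if (!is.na(bm) && abs(bm) > 1 + 1e-9)
        stop("bm must lie in [-1, 1]")
    (bm + 1) / 2
}

#' MCC as a difference of geometric means of the basic rates
#'
#' `MCC = sqrt(PPV*TPR*TNR*NPV) - sqrt(FDR*FNR*FPR*FOR)`. This form shows
#' that a high MCC requires all four basic rates to be high. Requires all
#' eight rates to be defined; `NA` otherwise.
#'
#' @param panel a [MetricPanel-class] (or a named vector holding the eight
#'   basic rates).
#' @return MCC in `[-1, 1]`, or `NA` if any input rate is undefined.
#' @examples
#' mccProductForm(metricPanel(ConfusionMatrix(100, 1, 5000, 94900)))
#' @export
mccProductForm <- function(panel) {
    r <- if (is(panel, "MetricPanel")) panel@values else panel
    need <- c("tpr", "tnr", "ppv", "npv", "fdr", "fnr", "fpr", "for")
    r <- r[need]
    if (anyNA(r)) return(NA_real_)
    sqrt(r[["ppv"]] * r[["tpr"]] * r[["tnr"]] * r[["npv"]]) -
        sqrt(r[["fdr"]] * r[["fnr"]] * r[["fpr"]] * r[["for"]])
}

.checkOpen01 <- function(phi, beta) {
    if (anyNA(c(phi, beta))) stop("phi and beta must not be NA")
    if (phi <= 0 || phi >= 1 || beta <= 0 || beta >= 1) NA_real_ else 0
}

#' MCC, BM and MK linked through prevalence and bias
#'
#' The three multi-category metrics differ only by prefactors built from
#' the prevalence `phi` and the bias `beta`:
#' * `MCC = sqrt((phi - phi^2)/(beta - beta^2)) * BM`
#' * `MCC = sqrt((beta - beta^2)/(phi - phi^2)) * MK`
#' * `MK  = ((phi - phi^2)/(beta - beta^2)) * BM`
#'
#' The prefactors are positive, so MCC, BM and MK always share their sign;
#' when `phi = beta` all three coincide. If the imbalance of the dataset
#' `|0.5 - phi|` exceeds the imbalance of the predictions `|0.5 - beta|`,
#' then `|MCC| < |BM|` and `|MCC| > |MK|`, and vice versa. On the boundary
#' (`phi` or `beta` in `{0, 1}`) the prefactors are undefined and `NA` is
#' returned.
#'
#' @param bm,mk metric values in `[-1, 1]`.
#' @param phi prevalence in `(0, 1)`.
#' @param beta bias in `(0, 1)`.
#' @return A single number, or `NA` on the boundary.
#' @examples
#' cm <- ConfusionMatrix(100, 1, 5000, 94900)
#' mccFromBM(bookmaker(cm), prevalence(cm), bias(cm))  # = mcc(cm)
#' @name metricBridges
#' @rdname metricBridges
NULL

#' @rdname metricBridges
#' @export
mccFromBM <- function(bm, phi, beta) {
    if (!is.na(b <- .checkOpen01(phi, beta))) {
        sqrt((phi - phi^2) / (beta - beta^2)) * bm
    } else NA_real_
}

#' @rdname metricBridges
#' @export
mccFromMK <- function(mk, phi, beta) {
    if (!is.na(b <- .checkOpen01(phi, beta))) {
        sqrt((beta - beta^2) / (phi - phi^2)) * mk
    } else NA_real_
}

#' @rdname metricBridges
#' @export
mkFromBM <- function(bm, phi, beta) {
    if (!is.na(b <- .checkOpen01(phi, beta))) {
        (phi - phi^2) / (beta - beta^2) * bm
    } else NA_real_
}

#' MCC as the geometric mean of informedness and markedness
#'
#' `MCC = sign(BM) * sqrt(BM * MK)`. BM and MK from one matrix always
#' share their sign, which resolves the sign of the square root; inputs of
#' strictly opposite sign cannot come from a single matrix and raise an
#' error.
#'
#' @param bm,mk metric values in `[-1, 1]` with `bm * mk >= 0`.
#' @return MCC in `[-1, 1]`; `NA` propagates.
#' @examples
#' mccGeometricMean(0.091, 10 / 11 / (90010 / 90011))  # CM3: ~0.301
#' @export
mccGeometricMean <- function(bm, mk) {
    if (is.na(bm) || is.na(mk)) return(NA_real_)
    if (bm * mk < 0)
        stop("bm and mk have opposite signs: inconsistent inputs ",
             "(metrics from one matrix always share their sign)")
    sign(bm) * sqrt(bm * mk)
}

#' Randomness index of a classifier
#'
#' `1 - |BM|`: how close the classifier's behaviour is to random guessing.
#' Random guessing has BM = 0 and randomness 1; a perfect (or perfectly
#' inverted) classifier has randomness 0. BM — not MCC or MK — is the
#' metric that measures this without distortion by prevalence or bias.
#'
#' @param bm bookmaker informedness in `[-1, 1]`, or a
#'   [ConfusionMatrix-class]/[RelativeConfusionMatrix-class] whose BM is
#'   used.
#' @return A number in `[0, 1]`; `NA` when BM is undefined.
#' @examples
#' randomnessIndex(0.75)                          # 0.25
#' randomnessIndex(ConfusionMatrix(25, 25, 25, 25))  # 1
#' @export
randomnessIndex <- function(bm) {
    if (is(bm, "CMTable")) bm <- bookmaker(bm)
    1 - abs(bm)
}

#' Numerically verify every inter-metric identity on one matrix
#'
#' Evaluates both sides of each derived relationship — `BA = (BM+1)/2`,
#' the product form of MCC, the three prevalence/bias bridges, the
#' geometric-mean form, and the two expressions for the bias — and reports
#' the absolute error against the stated tolerance. Identities whose
#' inputs are undefined for the given matrix are reported as not
#' applicable instead of failing.
#'
#' @param cm a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @param tol absolute tolerance (default 1e-10).
#' @return A `data.frame` with columns `identity`, `lhs`, `rhs`,
#'   `abs_error`, `applicable`, `holds`.
#' @examples
#' checkAllIdentities(ConfusionMatrix(100, 1, 5000, 94900))
#' @export
checkAllIdentities <- function(cm, tol = .IDENTITY_TOL) {
    stopifnot(is(cm, "CMTable"))
    panel <- metricPanel(cm)
    v <- panel@values
    phi <- prevalence(cm); beta <- bias(cm)
    m <- v[["mcc"]]

    gm <- if (is.na(v[["bm"]]) || is.na(v[["mk"]]) ||
              v[["bm"]] * v[["mk"]] < 0) NA_real_
          else mccGeometricMean(v[["bm"]], v[["mk"]])
    betaRate <- if (is.na(v[["tpr"]]) || is.na(v[["tnr"]])) NA_real_
                else v[["tpr"]] * phi + (1 - v[["tnr"]]) * (1 - phi)

    df <- data.frame(
        identity = c("BA = (BM+1)/2",
                     "MCC = product form",
                     "MCC = k(phi,beta) * BM",
                     "MCC = k(beta,phi) * MK",
                     "MK = k(phi,beta)^2 * BM",
                     "MCC = sign(BM)*sqrt(BM*MK)",
                     "beta: counts = rate form"),
        lhs = c(v[["ba"]], m, m, m, v[["mk"]], m, beta),
        rhs = c(baFromBM(v[["bm"]]),
                mccProductForm(panel),
                mccFromBM(v[["bm"]], phi, beta),
                mccFromMK(v[["mk"]], phi, beta),
                mkFromBM(v[["bm"]], phi, beta),
                gm, betaRate),
        stringsAsFactors = FALSE)
    df$abs_error <- abs(df$lhs - df$rhs)
    df$applicable <- !(is.na(df$lhs) | is.na(df$rhs))
    df$holds <- ifelse(df$applicable, df$abs_error <= tol, NA)
    df
}
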