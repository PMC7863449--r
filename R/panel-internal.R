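#' @include AllGenerics.R
NULL

## Vectorized metric kernel. All user-facing metric functions, the batch
## table, the enumeration module and the simulator funnel through here so
## that single-matrix and bulk results cannot disagree.
##
## `zeroTol`: a denominator is treated as zero when <= zeroTol. Counts are
## integers so the comparison is exact (zeroTol = 0); relative matrices are
## doubles and use .REL_TOL.

.safeDiv <- function(num, den, zeroTol) {
    out <- num / den
    out[den <= zeroTol] <- NA_real_
    out
}

## Total (zero-extended) MCC: the product-moment formula where defined,
## 0 whenever a marginal vanishes. Always returns a number.
.mccVec <- function(tp, fn, fp, tn, zeroTol = 0) {
    ## doubles throughout: marginal products overflow 32-bit integers
    tp <- as.numeric(tp); fn <- as.numeric(fn)
    fp <- as.numeric(fp); tn <- as.numeric(tn)
    num <- tp * tn - fp * fn
    p1 <- tp + fp; p2 <- tp + fn; p3 <- tn + fp; p4 <- tn + fn
    den <- sqrt(p1 * p2 * p3 * p4)
    degenerate <- p1 <= zeroTol | p2 <= zeroTol | p3 <= zeroTol | p4 <= zeroTol
    out <- numeric(length(num))
    out[!degenerate] <- num[!degenerate] / den[!degenerate]
    out
}

## All fourteen panel metrics, vectorized; returns a data.frame whose
## columns follow .PANEL_METRICS. NA encodes "undefined".
.panelVec <- function(tp, fn, fp, tn, zeroTol = 0) {
    tp <- as.numeric(tp); fn <- as.numeric(fn)
    fp <- as.numeric(fp); tn <- as.numeric(tn)
    tpr <- .safeDiv(tp, tp + fn, zeroTol)
    tnr <- .safeDiv(tn, tn + fp, zeroTol)
    ppv <- .safeDiv(tp, tp + fp, zeroTol)
    npv <- .safeDiv(tn, tn + fn, zeroTol)

    ba <- (tpr + tnr) / 2
    bm <- tpr + tnr - 1
    mk <- ppv + npv - 1
    acc <- (tp + tn) / (tp + fn + fp + tn)

    f1den <- ppv + tpr
    f1 <- 2 * ppv * tpr / f1den
    f1[!is.na(f1den) & f1den == 0] <- NA_real_

    data.frame(tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
               fdr = 1 - ppv, fnr = 1 - tpr, fpr = 1 - tnr, "for" = 1 - npv,
               mcc = .mccVec(tp, fn, fp, tn, zeroTol),
               ba = ba, bm = bm, mk = mk,
               accuracy = acc, f1 = f1,
               check.names = FALSE)
}

.zeroTolOf <- function(x) if (is(x, "RelativeConfusionMatrix")) .REL_TOL else 0

.panelOf <- function(x) {
    df <- .panelVec(x@tp, x@fn, x@fp, x@tn, .zeroTolOf(x))
    stats::setNames(as.numeric(df[1L, ]), names(df))
}

#' Compute every metric in the bundled table for many matrices at once
#'
#' Vectorized companion of [metricPanel()]: takes the four count columns
#' (or share columns for relative matrices) and returns one row per matrix
#' with the eight basic rates, MCC, BA, BM, MK, accuracy and F1. `NA`
#' marks an undefined metric; MCC uses the total zero-extension.
#'
#' @param cms a matrix or data frame with columns `tp`, `fn`, `fp`, `tn`
#'   (as produced by [enumerateCMs()] or [sampleCMs()]).
#' @param relative logical; `TRUE` when rows are shares rather than counts
#'   (switches the zero-denominator tolerance to 1e-12).
#' @return A `data.frame` with the four input columns followed by the
#'   fourteen metric columns.
#' @examples
#' metricTable(enumerateCMs(2))
#' @export
metricTable <- function(cms, relative = FALSE) {
    cms <- as.data.frame(cms)
    stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(cms)))
    zt <- if (relative) .REL_TOL else 0
    cbind(cms[c("tp", "fn", "fp", "tn")],
          .panelVec(cms$tp, cms$fn, cms$fp, cms$tn, zt))
}
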