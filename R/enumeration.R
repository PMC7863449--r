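#' @include identities.R
NULL

#' Enumerate every confusion matrix of a given sample size
#'
#' Generates all 4-tuples of non-negative integers `(tp, fn, fp, tn)`
#' summing to `n` — there are exactly `choose(n + 3, 3)` of them (stars
#' and bars) — each exactly once.
#'
#' @param n sample size, a positive integer.
#' @return An integer matrix with columns `tp`, `fn`, `fp`, `tn` and
#'   `choose(n + 3, 3)` rows.
#' @examples
#' nrow(enumerateCMs(2))  # 10
#' @export
enumerateCMs <- function(n) {
    if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
        stop("n must be a single positive integer")
    n <- as.integer(n)
    ## tp runs 0..n, fn runs 0..n-tp, fp runs 0..n-tp-fn, tn is forced
    tp <- rep.int(0:n, vapply(0:n, function(a) {
        m <- n - a; as.integer((m + 1) * (m + 2) / 2)
    }, integer(1)))
    fn <- unlist(lapply(0:n, function(a) {
        m <- n - a
        rep.int(0:m, (m:0) + 1L)
    }), use.names = FALSE)
    fp <- unlist(lapply(0:n, function(a) {
        m <- n - a
        unlist(lapply(0:m, function(b) 0:(m - b)), use.names = FALSE)
    }), use.names = FALSE)
    tn <- n - tp - fn - fp
    cbind(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Pearson correlation with pairwise deletion
#'
#' Standard product-moment correlation, computed from mean-centered
#' sufficient statistics (numerically safer than raw power sums); agrees
#' with [stats::cor()] to within 1e-12. Pairs where either value is `NA`
#' are dropped (pairwise deletion).
#'
#' @param xs,ys equal-length numeric vectors.
#' @return The correlation in `[-1, 1]`; `NA` (undefined) when fewer than
#'   two complete pairs remain or either side has zero variance.
#' @examples
#' pearsonCC(c(1, 2, 3), c(1, 2, 4))  # 0.98198...
#' @export
pearsonCC <- function(xs, ys) {
    if (length(xs) != length(ys))
        stop("xs and ys must have equal length")
    keep <- !(is.na(xs) | is.na(ys))
    x <- xs[keep]; y <- ys[keep]
    n <- length(x)
    if (n < 2L) return(NA_real_)
    sx <- sum(x); sy <- sum(y)
    ## center on the means before squaring: numerically safer than raw sums
    mx <- sx / n; my <- sy / n
    dx <- x - mx; dy <- y - my
    vx <- sum(dx * dx); vy <- sum(dy * dy)
    if (vx == 0 || vy == 0) return(NA_real_)
    sum(dx * dy) / sqrt(vx * vy)
}

#' Metric-correlation curve over exhaustive enumerations
#'
#' For each sample size `n`, enumerates all `choose(n + 3, 3)` confusion
#' matrices, computes MCC, BM and MK for every matrix, and returns the
#' three pairwise Pearson correlations. MCC is total (zero-extended) and
#' never excluded; a matrix is dropped from a pairwise correlation only
#' when the other metric of the pair is undefined (pairwise deletion);
#' `excluded` counts matrices with undefined BM or MK. The curve is high
#' (close to 1) throughout, dips to a minimum at moderate `n` and then
#' rises; `pcc_mcc_bm` and `pcc_mcc_mk` coincide for every `n` because
#' transposing a matrix (swapping FN and FP) exchanges BM and MK while
#' leaving MCC unchanged.
#'
#' @param nValues vector of sample sizes (each >= 2).
#' @return A `data.frame` with columns `n`, `count`, `excluded`,
#'   `pcc_mcc_bm`, `pcc_mcc_mk`, `pcc_bm_mk`.
#' @examples
#' pccCurve(5:10)
#' @export
pccCurve <- function(nValues) {
    if (any(is.na(nValues)) || any(nValues < 2))
        stop("each n must be >= 2")
    recs <- lapply(nValues, function(n) {
        cms <- enumerateCMs(n)
        met <- .panelVec(cms[, "tp"], cms[, "fn"], cms[, "fp"], cms[, "tn"])
        data.frame(
            n = n,
            count = nrow(cms),
            excluded = sum(is.na(met$bm) | is.na(met$mk)),
            pcc_mcc_bm = pearsonCC(met$mcc, met$bm),
            pcc_mcc_mk = pearsonCC(met$mcc, met$mk),
            pcc_bm_mk = pearsonCC(met$bm, met$mk))
    })
    do.call(rbind, recs)
}

#' Sample confusion matrices uniformly over compositions
#'
#' Draws `count` matrices uniformly from the set of all 4-part
#' compositions of `n` — the same measure the exhaustive enumeration uses
#' — via the stars-and-bars bijection with 3-subsets of `{1, ..., n+3}`.
#' Used to regenerate metric scatter clouds at a chosen sample count.
#'
#' @param count number of matrices to draw.
#' @param n sample size of every matrix.
#' @param seed optional integer seed for reproducibility.
#' @return An integer-valued matrix with columns `tp`, `fn`, `fp`, `tn`.
#' @examples
#' sampleCMs(5, n = 40000, seed = 1)
#' @export
sampleCMs <- function(count, n, seed = NULL) {
    stopifnot(count >= 1, n >= 1)
    if (!is.null(seed)) set.seed(seed)
    bars <- vapply(seq_len(count),
                   function(i) sort.int(sample.int(n + 3L, 3L)),
                   integer(3))
    tp <- bars[1L, ] - 1L
    fn <- bars[2L, ] - bars[1L, ] - 1L
    fp <- bars[3L, ] - bars[2L, ] - 1L
    tn <- n + 3L - bars[3L, ]
    cbind(tp = tp, fn = fn, fp = fp, tn = tn)
}
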