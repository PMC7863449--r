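#' @include enumeration.R
NULL

#' Simulate one classifier with a known amount of randomness
#'
#' The "exam cheating" generative model: `n` reference labels are drawn
#' positive with probability `phi`; a uniformly random subset of exactly
#' `round(lookup * n)` items is copied from the reference as the
#' prediction; every remaining item is predicted positive with probability
#' `guessBias`, independently. The lookup fraction is the known
#' informedness of the simulated classifier: in expectation
#' `TPR = lookup + (1-lookup)*guessBias` and
#' `TNR = lookup + (1-lookup)*(1-guessBias)`, hence `BM = lookup`
#' regardless of `phi` and `guessBias` — while MCC and MK drift away from
#' the lookup fraction whenever prevalence and bias are dissimilar.
#'
#' @param n number of items (exam questions).
#' @param phi prevalence of the positive reference class in `[0, 1]`.
#' @param lookup fraction of items copied from the reference in `[0, 1]`.
#' @param guessBias probability of guessing positive in `[0, 1]`. With
#'   `biasSemantics = "guess"` (default) it applies to the random portion
#'   only; with `"overall"` it is the target overall share of positive
#'   predictions, and the guess probability of the random portion is
#'   solved from `beta = lookup*phi + (1-lookup)*q` (clipped to `[0, 1]`).
#' @param fixedCounts if `TRUE`, draw exactly `round(phi * n)` positives
#'   in a random order instead of independent Bernoulli(`phi`) labels.
#' @param biasSemantics `"guess"` or `"overall"` (see `guessBias`).
#' @return A [ConfusionMatrix-class]. Seed the RNG (`set.seed`) for
#'   reproducibility.
#' @examples
#' set.seed(1)
#' cm <- simulateReplicate(10000, phi = 0.5, lookup = 0.75, guessBias = 0.5)
#' bookmaker(cm)  # close to 0.75
#' @export
simulateReplicate <- function(n, phi, lookup, guessBias,
                              fixedCounts = FALSE,
                              biasSemantics = c("guess", "overall")) {
    stopifnot(n >= 1, phi >= 0, phi <= 1, lookup >= 0, lookup <= 1,
              guessBias >= 0, guessBias <= 1)
    biasSemantics <- match.arg(biasSemantics)
    n <- as.integer(n)

    ref <- if (fixedCounts) {
        k <- as.integer(round(phi * n))
        sample(rep(c(TRUE, FALSE), c(k, n - k)))
    } else {
        stats::runif(n) < phi
    }

    q <- if (biasSemantics == "overall" && lookup < 1) {
        min(1, max(0, (guessBias - lookup * phi) / (1 - lookup)))
    } else guessBias

    pred <- stats::runif(n) < q
    nLook <- as.integer(round(lookup * n))
    if (nLook > 0L) {
        copied <- sample.int(n, nLook)
        pred[copied] <- ref[copied]
    }
    cmFromLabels(ref, pred, positive = TRUE)
}

#' Factorial grid of known-randomness simulations
#'
#' Runs [simulateReplicate()] `reps` times for every combination of
#' lookup fraction, prevalence and guess bias, and summarizes BM, MCC and
#' MK across replicates. Replicates where a reference class is absent
#' (possible at small `n * phi`) have undefined BM; they are excluded from
#' the summaries and counted in `n_excluded`.
#'
#' @param lookups,phis,biases numeric vectors of lookup fractions,
#'   prevalences and guess-bias values (full factorial grid).
#' @param n items per replicate.
#' @param reps replicates per cell.
#' @param seed integer seed; the full grid is reproducible from it.
#' @param fixedCounts,biasSemantics passed to [simulateReplicate()].
#' @return A `data.frame` with one row per cell: the cell parameters,
#'   `mean_bm`, `sd_bm`, `mean_mcc`, `sd_mcc`, `mean_mk`, `sd_mk`,
#'   `mean_beta` (realized bias), `n_used`, `n_excluded`.
#' @examples
#' randomnessGrid(lookups = c(0.25, 0.75), phis = 0.5, biases = 0.5,
#'                n = 2000, reps = 5, seed = 42)
#' @export
randomnessGrid <- function(lookups, phis, biases, n = 1e5, reps = 100,
                           seed = NULL, fixedCounts = FALSE,
                           biasSemantics = c("guess", "overall")) {
    biasSemantics <- match.arg(biasSemantics)
    if (!is.null(seed)) set.seed(seed)
    grid <- expand.grid(lookup = lookups, phi = phis, bias = biases,
                        KEEP.OUT.ATTRS = FALSE)
    out <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, ]
        bm <- mcc_ <- mk <- beta_ <- numeric(reps)
        for (r in seq_len(reps)) {
            cm <- simulateReplicate(n, g$phi, g$lookup, g$bias,
                                    fixedCounts = fixedCounts,
                                    biasSemantics = biasSemantics)
            p <- .panelOf(cm)
            bm[r] <- p[["bm"]]; mcc_[r] <- p[["mcc"]]; mk[r] <- p[["mk"]]
            beta_[r] <- bias(cm)
        }
        keep <- !is.na(bm)
        data.frame(lookup = g$lookup, phi = g$phi, bias = g$bias,
                   mean_bm = mean(bm[keep]), sd_bm = stats::sd(bm[keep]),
                   mean_mcc = mean(mcc_[keep]),
                   sd_mcc = stats::sd(mcc_[keep]),
                   mean_mk = mean(mk[keep], na.rm = TRUE),
                   sd_mk = stats::sd(mk[keep], na.rm = TRUE),
                   mean_beta = mean(beta_[keep]),
                   n_used = sum(keep), n_excluded = sum(!keep))
    })
    do.call(rbind, out)
}

#' Estimate the randomness of a classifier from its confusion matrix
#'
#' `1 - |BM|`, applied to an observed matrix: for a classifier generated
#' by the known-randomness model this recovers one minus the lookup
#' fraction, independent of prevalence and bias.
#'
#' @param cm a [ConfusionMatrix-class] or [RelativeConfusionMatrix-class].
#' @return A number in `[0, 1]`; `NA` when BM is undefined.
#' @examples
#' estimateRandomness(ConfusionMatrix(50, 0, 0, 50))  # 0: perfect
#' @export
estimateRandomness <- function(cm) {
    stopifnot(is(cm, "CMTable"))
    randomnessIndex(bookmaker(cm))
}
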