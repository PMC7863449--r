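#' @include io.R
NULL

.fmt3 <- function(x, precision = 3) {
    ifelse(is.na(x), "undefined",
           formatC(x, digits = precision, format = "f"))
}

#' Narrative numeric report for a worked-example fixture
#'
#' Renders the full analysis of one bundled fixture: the matrix, its
#' metric panel, the identity checks, and the fixture-specific findings —
#' for `"CM1"` the pre-/post-test probability table (prevalence, PPV,
#' 1-NPV) showing how much a positive or negative result shifts the
#' probability of disease; for `"CM2"` the disagreement between the
#' optimistic BA/BM and the near-zero MCC/MK; for `"CM3"` the
#' `MCC ~ sqrt(BM)` relationship that holds because MK ~ 1; for the UC4
#' fixtures the MCC-vs-BM ranking inversion.
#'
#' @param name fixture id, see [loadFixture()].
#' @param precision decimal places for display (default 3; values are
#'   computed at full precision).
#' @return Invisibly, a list with the computed pieces (`matrices`,
#'   `panels`, `identities`, and fixture-specific entries); called for
#'   its printed report.
#' @examples
#' rep <- useCaseReport("CM1")
#' rep$posttest_ratio   # ~19
#' @export
useCaseReport <- function(name, precision = 3) {
    cms <- loadFixture(name)
    panels <- lapply(cms, metricPanel)
    idents <- lapply(cms, checkAllIdentities)
    out <- list(matrices = cms, panels = panels, identities = idents)

    cat("== Use-case report:", name, "==\n\n")
    for (nm in names(cms)) {
        cat("--", nm, "--\n")
        show(cms[[nm]])
        show(panels[[nm]])
        ok <- idents[[nm]]$holds
        cat(sprintf("identities: %d hold, %d not applicable\n\n",
                    sum(ok, na.rm = TRUE), sum(is.na(ok))))
    }

    if (name == "CM1") {
        cm <- cms[[1L]]
        r <- basicRates(cm)
        phi <- prevalence(cm)
        ppv <- ppvFromRates(r[["tpr"]], r[["tnr"]], phi)
        oneMinusNpv <- 1 - npvFromRates(r[["tpr"]], r[["tnr"]], phi)
        out$pretest <- phi
        out$ppv <- ppv
        out$one_minus_npv <- oneMinusNpv
        out$posttest_ratio <- ppv / phi
        cat("Pre-/post-test probability of a positive instance:\n")
        cat(sprintf("  before testing   phi      %s\n", .fmt3(phi, precision)))
        cat(sprintf("  testing positive PPV      %s\n", .fmt3(ppv, precision)))
        cat(sprintf("  testing negative 1 - NPV  %s\n",
                    .fmt3(oneMinusNpv, 5)))
        cat(sprintf(
            "A positive result raises the probability by a factor of %.1f;\n",
            out$posttest_ratio))
        cat("a negative result makes disease extremely unlikely.\n")
    } else if (name == "CM2") {
        v <- panels[[1L]]@values
        out$optimistic <- v[c("ba", "bm")]
        out$pessimistic <- v[c("mcc", "mk")]
        cat(sprintf(
            "BA = %s and BM = %s suggest near-perfect prediction, but\n",
            .fmt3(v[["ba"]], precision), .fmt3(v[["bm"]], precision)))
        cat(sprintf(
            "MCC = %s and MK = %s expose the unreliable negative predictions\n",
            .fmt3(v[["mcc"]], precision), .fmt3(v[["mk"]], precision)))
        cat("(BA/BM misleading, MCC/MK informative for this matrix).\n")
    } else if (name == "CM3") {
        v <- panels[[1L]]@values
        out$sqrt_bm <- sqrt(v[["bm"]])
        cat(sprintf(
            "MK = %s is close to 1, so MCC = %s ~ sqrt(BM) = %s:\n",
            .fmt3(v[["mk"]], precision), .fmt3(v[["mcc"]], precision),
            .fmt3(out$sqrt_bm, precision)))
        cat("a moderate MCC despite an almost uninformed classifier.\n")
    } else {
        byMcc <- rankClassifiers(cms, "mcc")
        byBm <- rankClassifiers(cms, "bm")
        out$ranking_mcc <- byMcc
        out$ranking_bm <- byBm
        cat("Ranking by MCC:\n"); print(byMcc)
        cat("Ranking by BM:\n"); print(byBm)
        if (byMcc$name[1L] != byBm$name[1L])
            cat(sprintf(
                "The top classifier flips: %s leads by MCC, %s by BM.\n",
                byMcc$name[1L], byBm$name[1L]))
    }
    cat("\n")
    invisible(out)
}
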