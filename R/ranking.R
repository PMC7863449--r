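#' @include fixtures.R
NULL

.RANKABLE <- c("mcc", "ba", "bm", "mk", "accuracy", "f1",
               "tpr", "tnr", "ppv", "npv")

#' Rank classifiers by a chosen metric
#'
#' Orders a set of named confusion matrices by one metric, descending.
#' The sort is stable: ties keep input order and are reported in a shared
#' tie group. Classifiers whose metric is undefined cannot be ordered;
#' they are placed last and flagged. Different metrics can produce
#' different winners — ranking the `"UC4_separate"` fixture by MCC puts
#' classifier A first, ranking it by BM puts B first — which is why the
#' metric choice must match the question being asked.
#'
#' @param cms named list of [ConfusionMatrix-class] /
#'   [RelativeConfusionMatrix-class] objects (names label the
#'   classifiers).
#' @param metric one of `r paste0('"', .RANKABLE, '"', collapse = ", ")`.
#' @return A `data.frame` with columns `rank`, `name`, `value`,
#'   `tie_group` (equal values share a group id), `undefined`.
#' @examples
#' rankClassifiers(loadFixture("UC4_separate"), "mcc")  # A first
#' rankClassifiers(loadFixture("UC4_separate"), "bm")   # B first
#' @export
rankClassifiers <- function(cms, metric = "mcc") {
    if (length(cms) == 0L) stop("need at least one classifier")
    metric <- match.arg(tolower(metric), .RANKABLE)
    if (is.null(names(cms)) || any(!nzchar(names(cms))))
        names(cms) <- paste0("classifier", seq_along(cms))
    vals <- vapply(cms, function(cm) {
        stopifnot(is(cm, "CMTable"))
        .panelOf(cm)[[metric]]
    }, numeric(1))

    def <- !is.na(vals)
    ## stable descending sort on defined values; undefined appended last
    ordDef <- which(def)[order(-vals[def])]
    ord <- c(ordDef, which(!def))
    v <- vals[ord]
    ## new tie group when the value drops by more than numerical noise;
    ## all undefined entries share the final group
    vv <- ifelse(is.na(v), -Inf, v)
    d <- diff(vv)
    tie <- cumsum(c(TRUE, !is.nan(d) & d < -1e-12))

    data.frame(rank = seq_along(ord),
               name = names(cms)[ord],
               metric = metric,
               value = v,
               tie_group = tie,
               undefined = is.na(v),
               row.names = NULL,
               stringsAsFactors = FALSE)
}
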