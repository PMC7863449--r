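#' @include randomness-sim.R
NULL

## Worked-example matrices. CM1: screening test with high TPR/TNR on a
## very imbalanced dataset; CM2: its label-swapped analogue, where BA/BM
## are misleading; CM3: near-degenerate matrix where MK ~ 1 and
## MCC ~ sqrt(BM). UC4: two classifiers A and B whose MCC and BM rankings
## invert — "separate" holds A on dataset 1 and B on dataset 2 (the
## literature-comparison situation), "crossed" evaluates both on both.
.FIXTURES <- list(
    CM1 = list(list(name = "CM1", tp = 100, fn = 1, fp = 5000, tn = 94900)),
    CM2 = list(list(name = "CM2", tp = 90000, fn = 10000, fp = 1, tn = 9)),
    CM3 = list(list(name = "CM3", tp = 90000, fn = 0, fp = 10, tn = 1)),
    UC4_separate = list(
        list(name = "A@1", tp = 70, fn = 30, fp = 30, tn = 70),
        list(name = "B@2", tp = 8,  fn = 2,  fp = 38, tn = 152)),
    UC4_crossed = list(
        list(name = "A@1", tp = 70, fn = 30, fp = 30, tn = 70),
        list(name = "A@2", tp = 7,  fn = 3,  fp = 57, tn = 133),
        list(name = "B@1", tp = 80, fn = 20, fp = 20, tn = 80),
        list(name = "B@2", tp = 8,  fn = 2,  fp = 38, tn = 152)))

#' Bundled worked-example confusion matrices
#'
#' Returns the printed example matrices used throughout the package
#' documentation: `"CM1"` (tp=100, fn=1, fp=5000, tn=94900), `"CM2"`
#' (90000, 10000, 1, 9), `"CM3"` (90000, 0, 10, 1), and the two-classifier
#' comparison fixtures `"UC4_separate"` (classifier A on a balanced
#' dataset, classifier B on an imbalanced one; their MCC and BM rankings
#' invert) and `"UC4_crossed"` (both classifiers on both datasets).
#'
#' @param name one of `"CM1"`, `"CM2"`, `"CM3"`, `"UC4_separate"`,
#'   `"UC4_crossed"`.
#' @return A named list of [ConfusionMatrix-class] objects (length 1 for
#'   the single-matrix fixtures).
#' @examples
#' loadFixture("CM1")[[1]]
#' names(loadFixture("UC4_separate"))
#' @export
loadFixture <- function(name) {
    if (!name %in% names(.FIXTURES))
        stop("unknown fixture '", name, "'; available: ",
             paste(names(.FIXTURES), collapse = ", "))
    rows <- .FIXTURES[[name]]
    out <- lapply(rows, function(r)
        ConfusionMatrix(r$tp, r$fn, r$fp, r$tn))
    names(out) <- vapply(rows, `[[`, "", "name")
    out
}
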