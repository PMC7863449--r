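#' @include ranking.R
NULL

#' Read a batch of confusion matrices from CSV
#'
#' Expects columns `name,tp,fn,fp,tn`. Counts must be non-negative
#' integers. A relative-matrix file uses the same columns with
#' proportions and declares itself with the comment line
#' `# relative=true` as its first line; shares in each row must sum to 1.
#'
#' @param path path to the CSV file.
#' @return A named list of [ConfusionMatrix-class] (or
#'   [RelativeConfusionMatrix-class]) objects, with attribute
#'   `"relative"`.
#' @seealso [writeMetricCSV()] for the output side.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,tp,fn,fp,tn", "CM1,100,1,5000,94900"), f)
#' readCMBatch(f)
#' @export
readCMBatch <- function(path) {
    first <- readLines(path, n = 1L)
    relative <- grepl("^#.*relative\\s*=\\s*true", first, ignore.case = TRUE)
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    need <- c("name", "tp", "fn", "fp", "tn")
    if (!all(need %in% names(df)))
        stop("CSV must have columns: ", paste(need, collapse = ","))
    for (col in c("tp", "fn", "fp", "tn")) {
        v <- df[[col]]
        if (!is.numeric(v) || anyNA(v))
            stop("column '", col, "' must be numeric with no missing values")
        if (any(v < 0))
            stop("column '", col, "' contains negative values")
        if (!relative && any(v != round(v)))
            stop("column '", col, "' contains non-integer counts ",
                 "(declare '# relative=true' for share matrices)")
    }
    out <- lapply(seq_len(nrow(df)), function(i) {
        if (relative)
            RelativeConfusionMatrix(df$tp[i], df$fn[i], df$fp[i], df$tn[i])
        else
            ConfusionMatrix(df$tp[i], df$fn[i], df$fp[i], df$tn[i])
    })
    names(out) <- df$name
    attr(out, "relative") <- relative
    out
}

#' Write metric panels for a batch of matrices to CSV
#'
#' One row per matrix with columns
#' `name,tp,fn,fp,tn,tpr,tnr,ppv,npv,mcc,ba,bm,mk,accuracy,f1`.
#' Undefined metrics are serialized as the literal string `"undefined"`
#' (never silently substituted by a number).
#'
#' @param cms named list of confusion matrices (e.g. from
#'   [readCMBatch()]).
#' @param path output file path; `""` writes to stdout.
#' @param precision decimal places for the metric columns (default 3,
#'   matching conventional reporting); use `NA` for full precision.
#' @return Invisibly, the output `data.frame` (metrics still numeric).
#' @export
writeMetricCSV <- function(cms, path = "", precision = 3) {
    stopifnot(length(cms) >= 1)
    if (is.null(names(cms)))
        names(cms) <- paste0("cm", seq_along(cms))
    rows <- lapply(names(cms), function(nm) {
        cm <- cms[[nm]]
        p <- .panelOf(cm)
        data.frame(name = nm, tp = cm@tp, fn = cm@fn, fp = cm@fp, tn = cm@tn,
                   tpr = p[["tpr"]], tnr = p[["tnr"]],
                   ppv = p[["ppv"]], npv = p[["npv"]],
                   mcc = p[["mcc"]], ba = p[["ba"]],
                   bm = p[["bm"]], mk = p[["mk"]],
                   accuracy = p[["accuracy"]], f1 = p[["f1"]],
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    out <- df
    mcols <- setdiff(names(out), c("name", "tp", "fn", "fp", "tn"))
    for (col in mcols) {
        v <- out[[col]]
        if (!is.na(precision)) v <- round(v, precision)
        out[[col]] <- ifelse(is.na(v), "undefined", format(v, trim = TRUE))
    }
    utils::write.csv(out, file = path, row.names = FALSE, quote = FALSE)
    invisible(df)
}
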