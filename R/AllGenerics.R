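#' @include AllClasses.R
NULL

#' @rdname basicRates
#' @export
setGeneric("basicRates", function(x) standardGeneric("basicRates"))

#' @rdname mcc
#' @export
setGeneric("mcc", function(x) standardGeneric("mcc"))

#' @rdname multiCategoryMetrics
#' @export
setGeneric("balancedAccuracy",
           function(x) standardGeneric("balancedAccuracy"))

#' @rdname multiCategoryMetrics
#' @export
setGeneric("bookmaker", function(x) standardGeneric("bookmaker"))

#' @rdname multiCategoryMetrics
#' @export
setGeneric("markedness", function(x) standardGeneric("markedness"))

#' @rdname accuracyF1
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accuracyF1
#' @export
setGeneric("f1Score", function(x) standardGeneric("f1Score"))

#' @rdname metricPanel
#' @export
setGeneric("metricPanel", function(x) standardGeneric("metricPanel"))

#' @rdname swapLabels
#' @export
setGeneric("swapLabels", function(x) standardGeneric("swapLabels"))

#' @rdname prevalenceBias
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname prevalenceBias
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname rateParam
#' @export
setGeneric("rateParam", function(x) standardGeneric("rateParam"))

#' @rdname relativeForm
#' @export
setGeneric("relativeForm", function(x) standardGeneric("relativeForm"))
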