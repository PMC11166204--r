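#' Accessors for screen containers
#'
#' @param x a [BioidScreen-class] or [SimScreen-class].
#' @return `interactions` returns the records data.frame; `controlBaits` the
#'   named control map; `screenBaits`/`screenPreys` the non-control bait and
#'   prey identifiers; `cellLines` the cell lines present; `simTruth` the
#'   planted ground truth of a simulated screen.
#' @name screen-accessors
NULL

#' @rdname screen-accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname screen-accessors
#' @export
setGeneric("controlBaits", function(x) standardGeneric("controlBaits"))

#' @rdname screen-accessors
#' @export
setGeneric("screenBaits", function(x) standardGeneric("screenBaits"))

#' @rdname screen-accessors
#' @export
setGeneric("screenPreys", function(x) standardGeneric("screenPreys"))

#' @rdname screen-accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname screen-accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname screen-accessors
setMethod("interactions", "BioidScreen", function(x) x@records)

#' @rdname screen-accessors
setMethod("controlBaits", "BioidScreen", function(x) x@controlBaits)

#' @rdname screen-accessors
setMethod("screenBaits", "BioidScreen", function(x)
  sort(unique(x@records$bait[!x@records$is_control])))

#' @rdname screen-accessors
setMethod("screenPreys", "BioidScreen", function(x) sort(unique(x@records$prey)))

#' @rdname screen-accessors
setMethod("cellLines", "BioidScreen", function(x) unique(x@records$cell_line))

#' @rdname screen-accessors
setMethod("interactions", "SimScreen", function(x) x@screen@records)

#' @rdname screen-accessors
setMethod("controlBaits", "SimScreen", function(x) x@screen@controlBaits)

#' @rdname screen-accessors
setMethod("simTruth", "SimScreen", function(x) x@truth)

#' Accessors for cutpoint reports
#'
#' @param x a [CutpointReport-class].
#' @param method `"roc"` (Youden-optimal) or `"cda"` (maximum ECDF gap).
#' @return `cutpoint` returns the selected threshold, `rocAuc` the
#'   trapezoidal area under the ROC curve.
#' @name cutpoint-accessors
NULL

#' @rdname cutpoint-accessors
#' @export
setGeneric("cutpoint", function(x, method = "roc") standardGeneric("cutpoint"))

#' @rdname cutpoint-accessors
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))

#' @rdname cutpoint-accessors
setMethod("cutpoint", "CutpointReport", function(x, method = "roc") {
  method <- match.arg(method, c("roc", "cda"))
  if (method == "roc") x@rocCutpoint else x@cdaCutpoint
})

#' @rdname cutpoint-accessors
setMethod("rocAuc", "CutpointReport", function(x) x@auc)
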