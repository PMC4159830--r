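#' @rdname TagLibrary-class
#' @param x a \linkS4class{TagLibrary} or \linkS4class{CleanTagSet}
#' @export
setGeneric("tagKeys", function(x) standardGeneric("tagKeys"))

#' @rdname TagLibrary-class
#' @export
setGeneric("nTags", function(x) standardGeneric("nTags"))

#' @rdname TagLibrary-class
#' @export
setGeneric("tagHits", function(x) standardGeneric("tagHits"))

#' @rdname CleanTagSet-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname CleanTagSet-class
#' @export
setGeneric("rawTotal", function(x) standardGeneric("rawTotal"))

#' @rdname CleanTagSet-class
#' @export
setGeneric("cleanTotal", function(x) standardGeneric("cleanTotal"))

#' @rdname CleanTagSet-class
#' @export
setGeneric("cleaningReport", function(x) standardGeneric("cleaningReport"))

#' @rdname DgeExperiment-class
#' @param x a \linkS4class{DgeExperiment}
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname DgeExperiment-class
#' @export
setGeneric("mappingSummary", function(x) standardGeneric("mappingSummary"))

setMethod("tagKeys", "TagLibrary", function(x) x@tagInfo$tag)
setMethod("nTags", "TagLibrary", function(x) nrow(x@tagInfo))
setMethod("tagHits", "TagLibrary", function(x) x@hits)
setMethod("tagKeys", "CleanTagSet", function(x) x@tags$tag)
setMethod("nTags", "CleanTagSet", function(x) nrow(x@tags))
setMethod("tagCounts", "CleanTagSet", function(x) x@tags)
setMethod("rawTotal", "CleanTagSet", function(x) x@rawTotal)
setMethod("cleanTotal", "CleanTagSet", function(x) x@cleanTotal)
setMethod("cleaningReport", "CleanTagSet", function(x) x@report)
setMethod("libSizes", "DgeExperiment", function(x) {
  setNames(x$clean_total, colnames(x))
})
setMethod("mappingSummary", "DgeExperiment", function(x) {
  S4Vectors::metadata(x)$mappingSummary
})

setMethod("show", "TagLibrary", function(object) {
  n_amb <- sum(!object@tagInfo$unambiguous)
  cat("TagLibrary with", nrow(object@tagInfo), "distinct CATG+17 keys (",
      nrow(object@hits), "hits;", n_amb, "ambiguous keys )\n")
})

setMethod("show", "CleanTagSet", function(object) {
  cat("CleanTagSet:", format(object@cleanTotal, big.mark = ","),
      "clean tags /", format(object@rawTotal, big.mark = ","), "reads;",
      nrow(object@tags), "distinct\n")
  rej <- object@report
  cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DgeExperiment", function(object) {
  callNextMethod()
  cat("clean_total:", paste(colnames(object),
      format(object$clean_total, big.mark = ","), sep = "=", collapse = ", "),
      "\n")
})
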