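#' @include AllClasses.R
NULL

#' @export
setGeneric("computePsi", function(x, ...) standardGeneric("computePsi"))

#' @export
setGeneric("partitionEqualExpression", function(x, ...)
  standardGeneric("partitionEqualExpression"))

#' @export
setGeneric("coverageRetentionRatio", function(x, ...)
  standardGeneric("coverageRetentionRatio"))

#' @export
setGeneric("exonCount", function(model) standardGeneric("exonCount"))

#' @export
setGeneric("intronCount", function(model) standardGeneric("intronCount"))

#' @export
setGeneric("cdsSequence", function(model) standardGeneric("cdsSequence"))

#' @export
setGeneric("refProtein", function(model) standardGeneric("refProtein"))

#' @export
setGeneric("exonCRange", function(model, exonIndex)
  standardGeneric("exonCRange"))

#' @export
setGeneric("intronSeq", function(model, intronIndex)
  standardGeneric("intronSeq"))
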