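#' @rdname ProbePanel-class
#' @param x,object a \code{ProbePanel}
#' @export
setGeneric("probeNames", function(x) standardGeneric("probeNames"))

#' @rdname ProbePanel-class
#' @export
setGeneric("probeSequences", function(x) standardGeneric("probeSequences"))

#' @rdname ProbePanel-class
#' @export
setGeneric("probeExpansions", function(x) standardGeneric("probeExpansions"))

#' @rdname ProbePanel-class
#' @export
setGeneric("probeLengths", function(x) standardGeneric("probeLengths"))

#' @rdname ScreenResult-class
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))

#' @rdname ScreenResult-class
#' @export
setGeneric("matchRecords", function(x) standardGeneric("matchRecords"))

#' @rdname ScreenResult-class
#' @export
setGeneric("fileSummaries", function(x) standardGeneric("fileSummaries"))
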