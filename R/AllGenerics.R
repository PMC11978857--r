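#' @rdname PeptideDb-class
#' @param object,x A CoFrag object.
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideDb-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname MsRun-class
#' @export
setGeneric("ms1Scans", function(x) standardGeneric("ms1Scans"))

#' @rdname MsRun-class
#' @export
setGeneric("ms2Scans", function(x) standardGeneric("ms2Scans"))

#' @rdname MsRun-class
#' @export
setGeneric("ms1Peaks", function(x) standardGeneric("ms1Peaks"))

#' @rdname MsRun-class
#' @export
setGeneric("ms2Peaks", function(x) standardGeneric("ms2Peaks"))

#' @rdname MsRun-class
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname PsmSet-class
#' @export
setGeneric("psmTable", function(x) standardGeneric("psmTable"))

#' @rdname PsmSet-class
#' @export
setGeneric("searchParams", function(x) standardGeneric("searchParams"))

#' @rdname FragmentIndex-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
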