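#' @rdname AlleleCounts-class
#' @param x an object.
#' @export
setGeneric("countsTable", function(x) standardGeneric("countsTable"))

#' @rdname TriageReport-class
#' @param x an object.
#' @export
setGeneric("triageReport", function(x) standardGeneric("triageReport"))

#' @rdname AEITable-class
#' @param x an object.
#' @export
setGeneric("aeiRecords", function(x) standardGeneric("aeiRecords"))

#' @rdname AEITable-class
#' @export
setGeneric("aeiExclusions", function(x) standardGeneric("aeiExclusions"))

#' @rdname ErrorCurve-class
#' @param x an object.
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' Look up the error bound for a given read depth
#'
#' Step interpolation on an [ErrorCurve-class]: the bound at the largest
#' threshold X not exceeding `reads`. Depths below the smallest
#' threshold return the largest (most conservative) bound with a warning.
#'
#' @param x an [ErrorCurve-class].
#' @param reads numeric vector of read depths.
#' @return numeric vector of error bounds E (log2 units).
#' @export
setGeneric("errorAt", function(x, reads) standardGeneric("errorAt"))

#' @rdname RegulatoryModel-class
#' @param x an object.
#' @export
setGeneric("modelVariants", function(x) standardGeneric("modelVariants"))

#' @rdname RegulatoryModel-class
#' @export
setGeneric("markerFreq", function(x) standardGeneric("markerFreq"))

#' @rdname RegulatoryModel-class
#' @export
setGeneric("noiseSd", function(x) standardGeneric("noiseSd"))

#' @rdname AmpliconPanel-class
#' @param x an object.
#' @export
setGeneric("panelReference", function(x) standardGeneric("panelReference"))

#' @rdname AmpliconPanel-class
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))
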