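#' @rdname AmpliconPanel-class
#' @export
setMethod("panelReference", "AmpliconPanel", function(x) x@reference)

#' @rdname AmpliconPanel-class
#' @export
setMethod("indexMap", "AmpliconPanel", function(x) x@indexMap)

#' @rdname AlleleCounts-class
#' @export
setMethod("countsTable", "AlleleCounts", function(x) x@counts)

#' @rdname AlleleCounts-class
#' @export
setMethod("triageReport", "AlleleCounts", function(x) x@triage)

#' @rdname AEITable-class
#' @export
setMethod("aeiRecords", "AEITable", function(x) x@records)

#' @rdname AEITable-class
#' @export
setMethod("aeiExclusions", "AEITable", function(x) x@exclusions)

#' @rdname ErrorCurve-class
#' @export
setMethod("curvePoints", "ErrorCurve", function(x) x@points)

#' @rdname RegulatoryModel-class
#' @export
setMethod("modelVariants", "RegulatoryModel", function(x) x@variants)

#' @rdname RegulatoryModel-class
#' @export
setMethod("markerFreq", "RegulatoryModel", function(x) x@markerFreq)

#' @rdname RegulatoryModel-class
#' @export
setMethod("noiseSd", "RegulatoryModel", function(x) x@noiseSd)

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel with", nrow(object@reference), "gene(s) and",
      nrow(object@indexMap), "sample index(es)\n")
  len <- nchar(object@reference$amplicon_seq)
  cat("  amplicon length:", min(len), "-", max(len), "bp\n")
})

setMethod("show", "TriageReport", function(object) {
  tot <- max(object@totalReads, 1L)
  cat("TriageReport:", object@totalReads, "reads\n")
  cat(sprintf("  failed match     : %d (%.1f%%)\n", object@failedMatch,
              100 * object@failedMatch / tot))
  cat(sprintf("  missing mSNP base: %d (%.1f%%)\n", object@missingMsnpBase,
              100 * object@missingMsnpBase / tot))
  cat(sprintf("  usable           : %d (%.1f%%)\n", object@usable,
              100 * object@usable / tot))
  cat(sprintf("  single-allele-only subset: %d\n", object@singleAlleleOnly))
})

setMethod("show", "AlleleCounts", function(object) {
  cts <- object@counts
  cat("AlleleCounts:", nrow(cts), "record(s),",
      length(unique(cts$gene)), "gene(s),",
      length(unique(cts$sample_id)), "sample(s)\n")
  if (nrow(cts))
    cat("  templates:", paste(sort(unique(cts$template)), collapse = ", "), "\n")
  if (nrow(object@exclusions))
    cat("  exclusions:", nrow(object@exclusions), "\n")
})

setMethod("show", "AEITable", function(object) {
  rec <- object@records
  cat("AEITable:", nrow(rec), "record(s)")
  if (nrow(rec)) {
    cat(" (", sum(rec$corrected), "corrected )")
    cat(sprintf("\n  log2 AEI range: [%.3f, %.3f]\n",
                min(rec$log2_ratio), max(rec$log2_ratio)))
  } else cat("\n")
  if (nrow(object@exclusions))
    cat("  exclusions:", nrow(object@exclusions), "\n")
})

setMethod("show", "ErrorCurve", function(object) {
  cat(sprintf("ErrorCurve at %.0f%% confidence, %d point(s)\n",
              100 * object@confidence, nrow(object@points)))
  print(object@points, row.names = FALSE)
})

setMethod("show", "RegulatoryModel", function(object) {
  cat(sprintf("RegulatoryModel: P(M) = %.3f, noise SD = %.3f, %d variant(s)\n",
              object@markerFreq, object@noiseSd, nrow(object@variants)))
  if (nrow(object@variants)) print(object@variants, row.names = FALSE)
})
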