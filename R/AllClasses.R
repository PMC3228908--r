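#' @import methods
NULL

DNA_BASES_STRICT <- c("A", "C", "G", "T")

validIndexSeqs <- function(idx) {
  if (any(nchar(idx) != 5L))
    return("index sequences must be exactly 5 bases")
  chars <- strsplit(idx, "", fixed = TRUE)
  if (!all(vapply(chars, function(x) all(x %in% DNA_BASES_STRICT), logical(1))))
    return("index sequences may contain only A, C, G, T")
  # redundant positions: base 1 must equal base 5 so that a single
  # substitution at either end remains recognizable
  if (!all(vapply(chars, function(x) x[1] == x[5], logical(1))))
    return("index base at position 1 must equal base at position 5")
  if (anyDuplicated(idx))
    return("index sequences must be unique within a run")
  NULL
}

#' AmpliconPanel: assay reference for an indexed amplicon run
#'
#' Bundles the per-gene amplicon reference (sequence, 0-based marker-SNP
#' offset, the two mSNP alleles and which allele forms the AEI
#' numerator) with the sample index map (5-bp indices with redundant
#' first/fifth base).
#'
#' @slot reference data.frame with columns `gene`, `amplicon_seq`,
#'   `msnp_offset` (0-based), `allele_M`, `allele_m`, `numerator_allele`.
#' @slot indexMap data.frame with columns `sample_id`, `index_seq`.
#' @export
setClass("AmpliconPanel",
  representation(reference = "data.frame", indexMap = "data.frame"))

setValidity("AmpliconPanel", function(object) {
  ref <- object@reference
  idx <- object@indexMap
  msgs <- character()
  need_ref <- c("gene", "amplicon_seq", "msnp_offset", "allele_M",
                "allele_m", "numerator_allele")
  miss <- setdiff(need_ref, names(ref))
  if (length(miss))
    return(paste("reference missing column(s):", paste(miss, collapse = ", ")))
  if (!all(names(idx) %in% c("sample_id", "index_seq")) ||
      !all(c("sample_id", "index_seq") %in% names(idx)))
    return("indexMap must have columns sample_id, index_seq")
  len <- nchar(ref$amplicon_seq)
  if (any(len < 66L | len > 100L))
    msgs <- c(msgs, "amplicon sequences must be 66-100 bases")
  if (any(ref$msnp_offset < 0L | ref$msnp_offset >= len))
    msgs <- c(msgs, "msnp_offset must lie within the amplicon (0-based)")
  if (any(ref$allele_M == ref$allele_m))
    msgs <- c(msgs, "allele_M and allele_m must differ")
  if (!all(ref$numerator_allele %in% c("M", "m")))
    msgs <- c(msgs, "numerator_allele must be 'M' or 'm'")
  if (anyDuplicated(ref$gene))
    msgs <- c(msgs, "gene names must be unique")
  im <- validIndexSeqs(idx$index_seq)
  if (!is.null(im)) msgs <- c(msgs, im)
  if (anyDuplicated(idx$sample_id))
    msgs <- c(msgs, "sample_id values must be unique")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TriageReport: read-level quality-control accounting
#'
#' Counts how reads of a run were triaged: failed reference matching
#' (including unassignable indices and too-short reads), matched but
#' missing an interpretable marker-SNP base, or usable for allele
#' counting. `singleAlleleOnly` counts usable reads belonging to
#' gene/sample pairs in which only one of the two mSNP alleles was ever
#' observed despite a heterozygous genotype call (a genotype-discordance
#' signal); it is a subset of `usable`, not a fourth category.
#'
#' @slot totalReads,failedMatch,missingMsnpBase,singleAlleleOnly,usable
#'   non-negative integer counts; `totalReads = failedMatch +
#'   missingMsnpBase + usable`.
#' @slot lengthHistogram named integer vector mapping read length to count.
#' @export
setClass("TriageReport",
  representation(totalReads = "integer", failedMatch = "integer",
                 missingMsnpBase = "integer", singleAlleleOnly = "integer",
                 usable = "integer", lengthHistogram = "integer"))

setValidity("TriageReport", function(object) {
  cnts <- c(object@totalReads, object@failedMatch, object@missingMsnpBase,
            object@singleAlleleOnly, object@usable)
  if (any(cnts < 0L)) return("all triage counts must be non-negative")
  if (object@totalReads !=
      object@failedMatch + object@missingMsnpBase + object@usable)
    return("totalReads must equal failedMatch + missingMsnpBase + usable")
  if (object@singleAlleleOnly > object@usable)
    return("singleAlleleOnly is a subset of usable reads")
  TRUE
})

#' AlleleCounts: marker-SNP allele counts per sample, gene and template
#'
#' One row per (sample, gene, template) combination with the number of
#' reads supporting the M and m alleles of the marker SNP. Records are
#' kept only for samples genotyped heterozygous at the gene's mSNP;
#' excluded sample/gene pairs are retained with a reason.
#'
#' @slot counts data.frame with columns `sample_id`, `gene`, `template`
#'   (one of `"gDNA"`, `"cDNA"`), `count_M`, `count_m`,
#'   `single_allele_only` (logical).
#' @slot triage a [TriageReport-class] when counts came from reads, else NULL.
#' @slot exclusions data.frame (`sample_id`, `gene`, `reason`).
#' @export
setClass("AlleleCounts",
  representation(counts = "data.frame", triage = "ANY",
                 exclusions = "data.frame"))

setValidity("AlleleCounts", function(object) {
  cts <- object@counts
  need <- c("sample_id", "gene", "template", "count_M", "count_m")
  miss <- setdiff(need, names(cts))
  if (length(miss))
    return(paste("counts missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(cts)) {
    if (!all(cts$template %in% c("gDNA", "cDNA")))
      return("template must be 'gDNA' or 'cDNA'")
    if (any(cts$count_M < 0 | cts$count_m < 0))
      return("allele counts must be non-negative")
  }
  if (!is.null(object@triage) && !is(object@triage, "TriageReport"))
    return("triage must be a TriageReport or NULL")
  TRUE
})

#' AEITable: allelic expression imbalance ratios
#'
#' One row per (sample, gene, template) with the linear AEI ratio
#' (numerator-allele count / denominator-allele count), its log2, the
#' total read depth, the correction state and, once called, the
#' significance category.
#'
#' @slot records data.frame with columns `sample_id`, `gene`, `template`,
#'   `ratio`, `log2_ratio`, `total_reads`, `corrected`, and after
#'   [callSignificance()] also `call` and `threshold_used`.
#' @slot exclusions data.frame (`sample_id`, `gene`, `template`, `reason`)
#'   for records that could not form a ratio (a zero allele count).
#' @export
setClass("AEITable",
  representation(records = "data.frame", exclusions = "data.frame"))

setValidity("AEITable", function(object) {
  rec <- object@records
  need <- c("sample_id", "gene", "template", "ratio", "log2_ratio",
            "total_reads", "corrected")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("records missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    if (any(rec$ratio <= 0)) return("AEI ratios must be strictly positive")
    if (max(abs(rec$log2_ratio - log2(rec$ratio))) > 1e-8)
      return("log2_ratio must equal log2(ratio)")
  }
  TRUE
})

#' ErrorCurve: empirical measurement-error bound vs read depth
#'
#' A monotone non-increasing step curve giving, for each read-count
#' threshold X, the bound E (log2 units) such that the chosen fraction
#' of |log2 AEI| values among gDNA measurements with more than X reads
#' falls within [-E, E] (the "rectangle" construction).
#'
#' @slot confidence confidence level, e.g. 0.95 or 0.99.
#' @slot points data.frame with ordered columns `X` (read threshold) and
#'   `E` (error bound, log2 units), `E` non-increasing in `X`.
#' @export
setClass("ErrorCurve",
  representation(confidence = "numeric", points = "data.frame"))

setValidity("ErrorCurve", function(object) {
  if (length(object@confidence) != 1 || object@confidence <= 0 ||
      object@confidence >= 1)
    return("confidence must be a single value in (0, 1)")
  pts <- object@points
  if (!all(c("X", "E") %in% names(pts)))
    return("points must have columns X and E")
  if (nrow(pts) == 0) return("error curve must contain at least one point")
  if (is.unsorted(pts$X, strictly = TRUE))
    return("X thresholds must be strictly increasing")
  if (any(diff(pts$E) > 1e-12))
    return("E must be non-increasing in X")
  if (any(pts$E <= 0)) return("error bounds must be positive")
  TRUE
})

#' RegulatoryModel: cis-regulatory architecture behind a log2AEI distribution
#'
#' Describes the marker SNP and up to four cis-acting regulatory
#' variants. Each variant has a population frequency `P` of the
#' high-expression allele, a signed additive contribution `effect` (log2
#' units) when the high-expression allele sits on the M haplotype, and a
#' normalized linkage disequilibrium `dprime_marker` (D') to the marker
#' SNP. Optional pairwise D' between variants constrains the joint
#' haplotype distribution. Trans-acting variation and other unmodeled
#' factors enter only through the Gaussian `noiseSd` term (a pure trans
#' effect scales both alleles and cancels in the ratio).
#'
#' @slot markerFreq frequency of the M allele of the marker SNP, in (0,1).
#' @slot variants data.frame with columns `name`, `P`, `effect`,
#'   `dprime_marker`.
#' @slot pairwiseDprime NULL, or a named symmetric matrix of D' between
#'   variants (NA entries unconstrained).
#' @slot noiseSd non-negative Gaussian noise SD on the log2 scale.
#' @export
setClass("RegulatoryModel",
  representation(markerFreq = "numeric", variants = "data.frame",
                 pairwiseDprime = "ANY", noiseSd = "numeric"))

setValidity("RegulatoryModel", function(object) {
  p <- object@markerFreq
  if (length(p) != 1 || p <= 0 || p >= 1)
    return("markerFreq must be a single frequency in (0, 1)")
  v <- object@variants
  need <- c("name", "P", "effect", "dprime_marker")
  miss <- setdiff(need, names(v))
  if (length(miss))
    return(paste("variants missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(v) > 4)
    return("at most 4 regulatory variants (exact enumeration regime)")
  if (nrow(v)) {
    if (any(v$P <= 0 | v$P >= 1))
      return("variant frequencies must lie in (0, 1)")
    if (any(abs(v$dprime_marker) > 1))
      return("D' to the marker must lie in [-1, 1]")
    if (any(!is.finite(v$effect)))
      return("variant effects must be finite")
    if (anyDuplicated(v$name)) return("variant names must be unique")
  }
  if (!is.null(object@pairwiseDprime)) {
    m <- object@pairwiseDprime
    if (!is.matrix(m) || is.null(rownames(m)) ||
        !all(rownames(m) %in% v$name) || !all(colnames(m) %in% v$name))
      return("pairwiseDprime must be a matrix named by variant")
    if (any(abs(m) > 1, na.rm = TRUE))
      return("pairwise D' must lie in [-1, 1]")
  }
  if (length(object@noiseSd) != 1 || object@noiseSd < 0)
    return("noiseSd must be a single non-negative value")
  TRUE
})
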