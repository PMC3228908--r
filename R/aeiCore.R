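## AEI ratio computation and gDNA-based bias correction.
##
## The AEI ratio of a heterozygous sample is the amount of transcript
## from one allele divided by the amount from the other; per-gene
## numerator/denominator assignment comes from the amplicon reference.
## Genomic DNA from a heterozygote carries the alleles 1:1 by
## construction, so per-gene deviations of gDNA ratios from 1 measure
## allele-specific PCR amplification bias and define the correction.

#' Compute AEI ratios from allele counts
#'
#' Forms the linear ratio (numerator-allele count over
#' denominator-allele count) and its log2 for every count record with
#' both alleles observed. Records with a zero allele count cannot form a
#' ratio and are excluded with a reason (no pseudocount by default;
#' `pseudocount = 0.5` adds half a read to each allele instead).
#'
#' @param counts an [AlleleCounts-class] or its counts data.frame.
#' @param panel an [AmpliconPanel-class] (or a data.frame with columns
#'   `gene`, `numerator_allele`) giving each gene's numerator allele.
#' @param pseudocount value added to both counts before forming ratios
#'   (default 0, i.e. zero-count records are excluded).
#' @return an [AEITable-class] with `corrected = FALSE` records.
#' @examples
#' cts <- data.frame(sample_id = "s1", gene = "G1", template = "cDNA",
#'                   count_M = 600L, count_m = 400L)
#' ref <- data.frame(gene = "G1", numerator_allele = "M")
#' aeiRecords(computeAEI(cts, ref))   # ratio 1.5, log2 ~0.585
#' @export
computeAEI <- function(counts, panel, pseudocount = 0) {
  cts <- if (is(counts, "AlleleCounts")) countsTable(counts) else counts
  ref <- if (is(panel, "AmpliconPanel")) panelReference(panel) else panel
  stopifnot_cols(ref, c("gene", "numerator_allele"), "reference")
  num <- ref$numerator_allele[match(cts$gene, ref$gene)]
  if (anyNA(num))
    stop("genes without a reference entry: ",
         paste(unique(cts$gene[is.na(num)]), collapse = ", "))
  cM <- cts$count_M + pseudocount
  cm <- cts$count_m + pseudocount
  bad <- cM == 0 | cm == 0
  excl <- data.frame(sample_id = cts$sample_id[bad], gene = cts$gene[bad],
                     template = cts$template[bad],
                     reason = rep("zero_allele_count", sum(bad)),
                     stringsAsFactors = FALSE)
  keep <- !bad
  ratio <- ifelse(num == "M", cM / cm, cm / cM)[keep]
  rec <- data.frame(sample_id = cts$sample_id[keep], gene = cts$gene[keep],
                    template = cts$template[keep], ratio = ratio,
                    log2_ratio = log2(ratio),
                    total_reads = cts$count_M[keep] + cts$count_m[keep],
                    corrected = FALSE, stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  new("AEITable", records = rec, exclusions = excl)
}

#' Per-gene PCR amplification-bias correction factors
#'
#' Each gene's factor is the inverse of the arithmetic mean of its
#' uncorrected gDNA linear ratios, so that after multiplication the
#' gene's mean corrected gDNA ratio is exactly 1. A geometric-mean
#' variant (the log2-symmetric alternative) is available via `mean`.
#'
#' @param aei an [AEITable-class] containing gDNA records.
#' @param mean `"arithmetic"` (default) or `"geometric"`.
#' @return data.frame with columns `gene`, `factor`, `n_gdna_samples`.
#' @export
fitCorrectionFactors <- function(aei, mean = c("arithmetic", "geometric")) {
  mean <- match.arg(mean)
  rec <- aeiRecords(aei)
  g <- rec[rec$template == "gDNA", , drop = FALSE]
  if (!nrow(g)) stop("no gDNA records to derive correction factors from")
  if (any(g$corrected))
    stop("correction factors must be fit on uncorrected gDNA ratios")
  avg <- if (mean == "arithmetic") {
    tapply(g$ratio, g$gene, base::mean)
  } else {
    exp(tapply(log(g$ratio), g$gene, base::mean))
  }
  out <- data.frame(gene = names(avg), factor = as.numeric(1 / avg),
                    n_gdna_samples = as.integer(table(g$gene)[names(avg)]),
                    stringsAsFactors = FALSE)
  few <- out$gene[out$n_gdna_samples < 3L]
  if (length(few))
    warning("correction factor based on fewer than 3 gDNA samples for: ",
            paste(few, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Apply per-gene correction factors
#'
#' Multiplies every ratio (gDNA and cDNA alike) by its gene's factor and
#' recomputes the log2. Genes without a factor are dropped from the
#' corrected output (and listed in the exclusions); records already
#' corrected are rejected to prevent double application.
#'
#' @param aei an [AEITable-class] of uncorrected records.
#' @param factors data.frame from [fitCorrectionFactors()].
#' @return an [AEITable-class] with `corrected = TRUE` records.
#' @export
applyCorrection <- function(aei, factors) {
  rec <- aeiRecords(aei)
  if (any(rec$corrected))
    stop("records are already corrected; refusing to apply factors twice")
  f <- factors$factor[match(rec$gene, factors$gene)]
  nof <- is.na(f)
  excl <- aeiExclusions(aei)
  if (any(nof))
    excl <- rbind(excl,
                  data.frame(sample_id = rec$sample_id[nof],
                             gene = rec$gene[nof],
                             template = rec$template[nof],
                             reason = "no_correction_factor",
                             stringsAsFactors = FALSE))
  rec <- rec[!nof, , drop = FALSE]
  rec$ratio <- rec$ratio * f[!nof]
  rec$log2_ratio <- log2(rec$ratio)
  rec$corrected <- TRUE
  rownames(rec) <- NULL
  new("AEITable", records = rec, exclusions = excl)
}

#' Call per-sample AEI significance
#'
#' Classifies each corrected record as `negative`, `non-significant` or
#' `positive` against a log2 threshold with strict inequalities (a
#' log2 ratio exactly at the threshold is non-significant). The default
#' threshold 0.29 corresponds to linear ratios below 0.82 or above 1.22,
#' the band containing 95% of normalized gDNA control ratios. With an
#' [ErrorCurve-class], each record instead uses the read-depth-dependent
#' bound for its own read total.
#'
#' @param aei an [AEITable-class] of corrected records.
#' @param threshold log2 threshold (default 0.29).
#' @param errorCurve optional [ErrorCurve-class] for depth-adaptive calls.
#' @return the [AEITable-class] with `call` and `threshold_used` columns.
#' @export
callSignificance <- function(aei, threshold = 0.29, errorCurve = NULL) {
  rec <- aeiRecords(aei)
  if (nrow(rec) && !all(rec$corrected))
    stop("significance is called on corrected records only")
  thr <- if (is.null(errorCurve)) rep(threshold, nrow(rec))
         else errorAt(errorCurve, rec$total_reads)
  rec$call <- ifelse(rec$log2_ratio < -thr, "negative",
                     ifelse(rec$log2_ratio > thr, "positive",
                            "non-significant"))
  rec$threshold_used <- thr
  initialize(aei, records = rec)
}

#' Summarize AEI patterns per gene
#'
#' For each gene's corrected cDNA records: the number of heterozygous
#' samples measured, the fractions of samples with negative,
#' non-significant and positive calls, and the extreme log2 ratios.
#'
#' @param aei a called [AEITable-class] (see [callSignificance()]).
#' @return data.frame with columns `gene`, `n_het_samples`,
#'   `frac_negative`, `frac_nonsig`, `frac_positive`, `min_log2`,
#'   `max_log2`.
#' @export
summarizeGenes <- function(aei) {
  rec <- aeiRecords(aei)
  if (is.null(rec$call)) stop("run callSignificance() first")
  cd <- rec[rec$template == "cDNA", , drop = FALSE]
  if (!nrow(cd)) stop("no corrected cDNA records to summarize")
  out <- do.call(rbind, lapply(split(cd, cd$gene), function(d) {
    n <- nrow(d)
    data.frame(gene = d$gene[1], n_het_samples = n,
               frac_negative = sum(d$call == "negative") / n,
               frac_nonsig = sum(d$call == "non-significant") / n,
               frac_positive = sum(d$call == "positive") / n,
               min_log2 = min(d$log2_ratio), max_log2 = max(d$log2_ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Study-level rollup of gene summaries
#'
#' Fractions of genes with any significant sample and with significant
#' AEI in at least `minFrac` of the cohort, plus a histogram of the
#' per-gene proportion of significant samples.
#'
#' @param summary data.frame from [summarizeGenes()].
#' @param nCohort cohort size used as the denominator for the
#'   `minFrac` criterion (the full sample collection, not just the
#'   heterozygotes; default `NULL` uses each gene's heterozygote count).
#' @param minFrac cohort fraction defining "frequent AEI" (default 0.2).
#' @param breaks histogram breaks on the proportion of significant
#'   heterozygous samples.
#' @return list with `n_genes`, `frac_any_significant`,
#'   `frac_frequent`, `frac_none`, and `histogram` (data.frame).
#' @export
summarizeStudy <- function(summary, nCohort = NULL, minFrac = 0.2,
                           breaks = seq(0, 1, by = 0.1)) {
  sig <- summary$frac_negative + summary$frac_positive
  nsig <- round(sig * summary$n_het_samples)
  denom <- if (is.null(nCohort)) summary$n_het_samples else nCohort
  h <- hist(sig, breaks = breaks, plot = FALSE)
  list(n_genes = nrow(summary),
       frac_any_significant = base::mean(nsig > 0),
       frac_frequent = base::mean(nsig / denom >= minFrac),
       frac_none = base::mean(nsig == 0),
       histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                              upper = h$breaks[-1], n_genes = h$counts))
}

#' Replicate concordance of independent AEI assays
#'
#' Ordinary least-squares regression of log2 AEI ratios from one assay
#' on those of an independent replicate, matched by sample within each
#' gene. Genes with fewer than 3 matched pairs are reported as
#' not-assessable; zero variance in either assay leaves r2 undefined.
#' Note that r2 is only informative for genes whose log2 AEI
#' distribution spans an appreciable range.
#'
#' @param aeiA,aeiB [AEITable-class] objects (cDNA records are used).
#' @return data.frame with columns `gene`, `n_pairs`, `slope`,
#'   `intercept`, `r2`, `assessable`.
#' @export
replicateConcordance <- function(aeiA, aeiB) {
  a <- aeiRecords(aeiA); a <- a[a$template == "cDNA", ]
  b <- aeiRecords(aeiB); b <- b[b$template == "cDNA", ]
  key <- function(d) paste(d$sample_id, d$gene)
  m <- match(key(a), key(b))
  paired <- !is.na(m)
  df <- data.frame(gene = a$gene[paired], x = a$log2_ratio[paired],
                   y = b$log2_ratio[m[paired]], stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$gene), function(d) {
    n <- nrow(d)
    if (n < 3L)
      return(data.frame(gene = d$gene[1], n_pairs = n, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_,
                        assessable = FALSE))
    if (stats::var(d$x) == 0 || stats::var(d$y) == 0)
      return(data.frame(gene = d$gene[1], n_pairs = n, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_,
                        assessable = FALSE))
    ## only coefficients and r2 are used, so the "perfect fit" warning
    ## on identical replicates is irrelevant here
    fit <- suppressWarnings(stats::lm(y ~ x, data = d))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(gene = d$gene[1], n_pairs = n,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = r2, assessable = TRUE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname readCounts
#' @param aei an [AEITable-class].
#' @export
writeAEI <- function(aei, path) writeTsv(aeiRecords(aei), path)
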