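## Pipeline orchestration: demultiplex/count -> correct -> call ->
## summarize, with explicit exclusion accounting and a provenance log.
## All quantitative outputs are TSV/JSON; figures are optional.

#' Run the AEI pipeline
#'
#' Executes the full analysis on either FASTQ inputs (gDNA and cDNA
#' runs) or precomputed allele-count tables: allele counting, AEI ratio
#' computation, gDNA-based bias correction, significance calling,
#' per-gene summaries and (optionally) an empirical error curve. Both
#' entry points yield identical downstream outputs on matched counts.
#'
#' @param config a named list or the path to a YAML file with entries:
#'   `reference`, `index_map`, `genotypes` (paths), then either
#'   `fastq_gdna` + `fastq_cdna` or `counts` (path to a combined counts
#'   TSV); optional `out_dir` (default `"aei_out"`), `threshold`
#'   (default 0.29), `confidence` (default 0.95), `index_mode`
#'   (default `"exact"`), `error_curve` (logical, default TRUE when
#'   enough gDNA records exist), `seed` (recorded for provenance).
#' @return invisibly, a list with `aei` (called [AEITable-class]),
#'   `factors`, `summary`, `study`, `errorCurve` (or NULL) and the
#'   output directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("reference", "genotypes")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing: ", paste(miss, collapse = ", "))
  from_fastq <- !is.null(config$fastq_gdna) || !is.null(config$fastq_cdna)
  paths <- unlist(config[intersect(names(config),
                                   c("reference", "index_map", "genotypes",
                                     "fastq_gdna", "fastq_cdna", "counts"))])
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  out_dir <- config$out_dir %||% "aei_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  threshold <- config$threshold %||% 0.29
  confidence <- config$confidence %||% 0.95
  log_lines <- character()
  logmsg <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genotypes <- stage("inputs", readGenotypes(config$genotypes))
  ## counts-only runs need just the numerator assignment; the full
  ## amplicon columns are required only when reads must be sorted
  ref <- if (from_fastq) {
    stage("inputs", readAmpliconReference(config$reference))
  } else {
    stage("inputs", stopifnot_cols(readTsv(config$reference),
                                   c("gene", "numerator_allele"),
                                   "reference table"))
  }

  triage <- NULL
  if (from_fastq) {
    if (is.null(config$fastq_gdna) || is.null(config$fastq_cdna))
      stop("both fastq_gdna and fastq_cdna are required for FASTQ input")
    if (is.null(config$index_map))
      stop("index_map is required for FASTQ input")
    panel <- stage("inputs",
                   AmpliconPanel(ref, readIndexMap(config$index_map)))
    cg <- stage("demux-count",
                countReads(config$fastq_gdna, panel, genotypes,
                           template = "gDNA",
                           indexMode = config$index_mode %||% "exact"))
    cc <- stage("demux-count",
                countReads(config$fastq_cdna, panel, genotypes,
                           template = "cDNA",
                           indexMode = config$index_mode %||% "exact"))
    logmsg("demux-count", "gDNA usable reads: ", triageReport(cg)@usable,
           "/", triageReport(cg)@totalReads)
    logmsg("demux-count", "cDNA usable reads: ", triageReport(cc)@usable,
           "/", triageReport(cc)@totalReads)
    counts <- new("AlleleCounts",
                  counts = rbind(countsTable(cg), countsTable(cc)),
                  triage = NULL,
                  exclusions = rbind(cg@exclusions, cc@exclusions))
    triage <- list(gDNA = triageReport(cg), cDNA = triageReport(cc))
    writeTriageJson(triage$gDNA, file.path(out_dir, "triage_gdna.json"))
    writeTriageJson(triage$cDNA, file.path(out_dir, "triage_cdna.json"))
  } else {
    if (is.null(config$counts))
      stop("either FASTQ inputs or a counts table is required")
    counts <- stage("inputs", readCounts(config$counts))
  }
  writeCounts(counts, file.path(out_dir, "counts.tsv"))
  logmsg("counts", nrow(countsTable(counts)), " count records, ",
         nrow(counts@exclusions), " exclusions")

  aei <- stage("aei", computeAEI(counts, ref))
  logmsg("aei", nrow(aeiRecords(aei)), " ratios formed, ",
         nrow(aeiExclusions(aei)), " excluded (zero allele count)")
  factors <- stage("correct", fitCorrectionFactors(aei))
  corrected <- stage("correct", applyCorrection(aei, factors))
  writeTsv(factors, file.path(out_dir, "correction_factors.tsv"))

  curve <- NULL
  gd <- aeiRecords(corrected)
  gd <- gd[gd$template == "gDNA", ]
  want_curve <- config$error_curve %||% (nrow(gd) >= 40L)
  if (isTRUE(want_curve)) {
    pts <- data.frame(log2_ratio = gd$log2_ratio, reads = gd$total_reads)
    curve <- tryCatch(buildErrorCurve(pts, confidence = confidence),
                      error = function(e) {
                        logmsg("error-curve", "skipped: ",
                               conditionMessage(e))
                        NULL
                      })
    if (!is.null(curve))
      writeErrorCurve(curve, file.path(out_dir, "error_curve.json"))
  }

  called <- stage("call", callSignificance(corrected, threshold = threshold))
  writeAEI(called, file.path(out_dir, "aei.tsv"))
  summary <- stage("summarize", summarizeGenes(called))
  writeTsv(summary, file.path(out_dir, "gene_summary.tsv"))
  study <- summarizeStudy(summary,
                          nCohort = length(unique(genotypes$sample_id)))
  logmsg("summarize", sprintf(
    "%d genes; %.0f%% with any significant sample; %.0f%% frequent AEI",
    study$n_genes, 100 * study$frac_any_significant,
    100 * study$frac_frequent))

  report <- list(
    package_version = as.character(utils::packageVersion("aeiscope")),
    r_version = as.character(getRversion()),
    parameters = list(threshold = threshold, confidence = confidence,
                      index_mode = config$index_mode %||% "exact",
                      seed = config$seed),
    inputs = as.list(paths),
    exclusions = counts@exclusions,
    aei_exclusions = aeiExclusions(called),
    study = study[c("n_genes", "frac_any_significant", "frac_frequent",
                    "frac_none")],
    log = log_lines)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(aei = called, factors = factors, summary = summary,
                 study = study, errorCurve = curve, triage = triage,
                 out_dir = out_dir))
}
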