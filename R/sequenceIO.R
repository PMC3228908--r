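## Read sorting for indexed amplicon runs.
##
## Reads are single-end: a 5-bp sample index followed by the amplicon
## insert in either orientation. Amplicons are short (66-100 bp) and
## indels are not modeled, so matching is ungapped identity over the
## aligned overlap with flank verification around the marker SNP.
## All coordinates are 0-based offsets internally; 1-based only at the
## boundary with substr()/Biostrings.

#' Read an indexed amplicon FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file (Sanger/Phred+33 qualities).
#' Qualities are carried along but not used for filtering; the only
#' length gate applied downstream is a minimum read length.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
readIndexedFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ: truncated record starting at line ",
         (n %/% 4L) * 4L + 1L)
  hdr <- seq(1L, n, by = 4L)
  plus <- hdr + 2L
  bad_hdr <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad_hdr))
    stop("malformed FASTQ: header without '@' at line ", bad_hdr[1])
  bad_plus <- plus[!startsWith(lines[plus], "+")]
  if (length(bad_plus))
    stop("malformed FASTQ: separator without '+' at line ", bad_plus[1])
  seqs <- toupper(lines[hdr + 1L])
  quals <- lines[hdr + 3L]
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len))
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         hdr[bad_len[1]] + 1L)
  ## round-trip through Biostrings validates the alphabet
  Biostrings::DNAStringSet(seqs)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[hdr])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

## character matrix (n x width) from variable-length strings, padded
## with NA beyond each string's length
seqCharMatrix <- function(seqs, width = max(nchar(seqs), 1L)) {
  n <- length(seqs)
  mat <- matrix(NA_character_, n, width)
  if (n == 0) return(mat)
  chars <- strsplit(seqs, "", fixed = TRUE)
  len <- pmin(nchar(seqs), width)
  for (i in seq_len(n)) if (len[i] > 0) mat[i, seq_len(len[i])] <- chars[[i]][seq_len(len[i])]
  mat
}

#' Assign reads to samples by their 5-bp index
#'
#' The index occupies the first five bases of each read. In `"exact"`
#' mode only perfect matches are assigned. In `"correct"` mode a single
#' substitution is tolerated when the redundant-position rule still
#' identifies the index: indices carry identical bases at positions 1
#' and 5, so an end-position error leaves the other copy intact, and an
#' interior error is accepted only if the read's own positions 1 and 5
#' agree. Reads tying between two indices are never assigned.
#'
#' @param sequences character vector of full read sequences.
#' @param indexMap data.frame with columns `sample_id`, `index_seq`.
#' @param mode `"exact"` (default) or `"correct"`.
#' @return character vector of sample ids, `NA` where unassigned.
#' @export
demultiplexReads <- function(sequences, indexMap,
                             mode = c("exact", "correct")) {
  mode <- match.arg(mode)
  im <- validIndexSeqs(indexMap$index_seq)
  if (!is.null(im)) stop(im)
  prefix <- substr(sequences, 1L, 5L)
  assigned <- indexMap$sample_id[match(prefix, indexMap$index_seq)]
  assigned[nchar(sequences) < 5L] <- NA_character_
  if (mode == "exact" || !anyNA(assigned)) return(assigned)

  todo <- which(is.na(assigned) & nchar(sequences) >= 5L)
  if (!length(todo)) return(assigned)
  pm <- seqCharMatrix(prefix[todo], 5L)
  idxchars <- strsplit(indexMap$index_seq, "", fixed = TRUE)
  nmatch <- matrix(0L, length(todo), nrow(indexMap))
  for (j in seq_len(nrow(indexMap))) {
    eq <- pm == matrix(idxchars[[j]], nrow(pm), 5L, byrow = TRUE)
    nmatch[, j] <- rowSums(eq, na.rm = TRUE)
  }
  best <- apply(nmatch, 1L, max)
  nbest <- rowSums(nmatch == best)
  cand <- max.col(nmatch, ties.method = "first")
  ok <- best == 4L & nbest == 1L
  if (any(ok)) {
    for (i in which(ok)) {
      j <- cand[i]
      mmpos <- which(pm[i, ] != idxchars[[j]])
      if (length(mmpos) != 1L) { ok[i] <- FALSE; next }
      if (mmpos %in% c(2L, 3L, 4L)) {
        # interior error: the read's redundant ends must still agree
        ok[i] <- identical(pm[i, 1L], pm[i, 5L])
      }
      # end-position error: the surviving redundant copy already matched
    }
  }
  assigned[todo[ok]] <- indexMap$sample_id[cand[ok]]
  assigned
}

#' Match inserts to the amplicon reference library
#'
#' Ungapped identity of each read (index already removed) against every
#' library sequence over their aligned overlap, anchored at the read
#' start. The best-identity entry wins; reads whose best identity falls
#' below `minIdentity`, reads shorter than `minReadLen`, and reads tying
#' across distinct genes are returned as no-match.
#'
#' @param sequences character vector of insert sequences.
#' @param library reference library from [buildReferenceLibrary()].
#' @param minIdentity minimum identity over the overlap (default 0.9).
#' @param minReadLen minimum usable insert length (default 30).
#' @return data.frame with columns `gene`, `orientation`, `identity`
#'   (`NA` rows are unmatched).
#' @export
matchReads <- function(sequences, library, minIdentity = 0.9,
                       minReadLen = 30L) {
  if (nrow(library) == 0) stop("reference library is empty")
  n <- length(sequences)
  out <- data.frame(gene = rep(NA_character_, n),
                    orientation = rep(NA_character_, n),
                    identity = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  len <- nchar(sequences)
  usable <- len >= minReadLen
  if (!any(usable)) return(out)
  width <- max(nchar(library$seq))
  mat <- seqCharMatrix(sequences, width)
  bestId <- rep(-1, n)
  bestGene <- rep(NA_character_, n)
  bestOri <- rep(NA_character_, n)
  tied <- rep(FALSE, n)
  eps <- 1e-9
  libchars <- strsplit(library$seq, "", fixed = TRUE)
  for (j in seq_len(nrow(library))) {
    lj <- length(libchars[[j]])
    eq <- mat[, seq_len(lj), drop = FALSE] ==
      matrix(libchars[[j]], n, lj, byrow = TRUE)
    matches <- rowSums(eq, na.rm = TRUE)
    ident <- matches / pmin(len, lj)
    better <- usable & ident > bestId + eps
    tie <- usable & abs(ident - bestId) <= eps & !better
    if (any(tie)) {
      other <- tie & (library$gene[j] != bestGene)
      tied[other] <- TRUE
      # same-gene tie (palindromic insert): keep the first orientation
    }
    if (any(better)) {
      bestId[better] <- ident[better]
      bestGene[better] <- library$gene[j]
      bestOri[better] <- library$orientation[j]
      tied[better] <- FALSE
    }
  }
  hit <- usable & bestId >= minIdentity & !tied
  out$gene[hit] <- bestGene[hit]
  out$orientation[hit] <- bestOri[hit]
  out$identity[hit] <- bestId[hit]
  out
}

#' Extract the marker-SNP allele from matched reads
#'
#' Orientation-normalizes each read onto its amplicon, reads off the
#' base at the marker-SNP offset and verifies up to `flankLen` bases of
#' flanking sequence on each side (truncated at read/amplicon ends).
#' Outcomes: `"M"`/`"m"` when the base equals an expected allele and
#' both flanks pass; `"neither"` when the covered base equals no
#' expected allele; `"missing"` when the read does not cover the marker
#' SNP; `"flank_fail"` when a flank exceeds `maxFlankMismatch`
#' mismatches.
#'
#' @param sequences character vector of insert sequences.
#' @param matches data.frame from [matchReads()] (same length).
#' @param panel an [AmpliconPanel-class].
#' @param flankLen flank length in bases (default 20).
#' @param maxFlankMismatch maximum mismatches tolerated per flank
#'   (default 2).
#' @return character vector of outcomes (`NA` for unmatched reads).
#' @export
extractAlleles <- function(sequences, matches, panel, flankLen = 20L,
                           maxFlankMismatch = 2L) {
  ref <- panelReference(panel)
  n <- length(sequences)
  out <- rep(NA_character_, n)
  hit <- which(!is.na(matches$gene))
  if (!length(hit)) return(out)
  key <- paste(matches$gene[hit], matches$orientation[hit])
  for (grp in split(hit, key)) {
    g <- matches$gene[grp[1]]
    ori <- matches$orientation[grp[1]]
    r <- ref[ref$gene == g, ]
    amp <- r$amplicon_seq
    L <- nchar(amp)
    offset <- r$msnp_offset                  # 0-based
    reads <- sequences[grp]
    if (ori == "revcomp")
      reads <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads)))
    rlen <- pmin(nchar(reads), L)
    reads <- substr(reads, 1L, L)
    ## aligned amplicon coordinates: forward reads start at position 1,
    ## orientation-normalized revcomp reads end at position L
    start <- if (ori == "forward") rep(1L, length(grp)) else L - rlen + 1L
    aligned <- matrix(NA_character_, length(grp), L)
    chars <- strsplit(reads, "", fixed = TRUE)
    for (i in seq_along(grp))
      aligned[i, seq(start[i], length.out = rlen[i])] <- chars[[i]]
    ampchars <- strsplit(amp, "", fixed = TRUE)[[1]]
    snp_col <- offset + 1L
    base <- aligned[, snp_col]
    res <- rep("missing", length(grp))
    covered <- !is.na(base)
    mism <- t(t(aligned) != ampchars)        # NA where not covered
    upcols <- seq(max(1L, snp_col - flankLen), length.out = min(flankLen, snp_col - 1L))
    dncols <- seq(snp_col + 1L, length.out = min(flankLen, L - snp_col))
    upmm <- if (length(upcols))
      rowSums(mism[, upcols, drop = FALSE], na.rm = TRUE) else 0
    dnmm <- if (length(dncols))
      rowSums(mism[, dncols, drop = FALSE], na.rm = TRUE) else 0
    flank_ok <- upmm <= maxFlankMismatch & dnmm <= maxFlankMismatch
    res[covered & !flank_ok] <- "flank_fail"
    res[covered & flank_ok] <-
      ifelse(base[covered & flank_ok] == r$allele_M, "M",
             ifelse(base[covered & flank_ok] == r$allele_m, "m", "neither"))
    out[grp] <- res
  }
  out
}

#' Tabulate allele counts from triaged reads
#'
#' Aggregates usable reads into one [AlleleCounts-class] record per
#' (sample, gene, template). Only samples genotyped heterozygous (`Mm`)
#' at a gene's marker SNP yield records; reads from samples that are
#' homozygous or absent from the genotype table are excluded with a
#' reason, as are heterozygous pairs with zero usable reads. Records in
#' which one allele count is zero are flagged `single_allele_only`
#' (a genotype-discordance signal).
#'
#' @param readTable data.frame with columns `sample_id`, `gene`,
#'   `allele` (values `"M"`/`"m"` are counted).
#' @param genotypes data.frame with columns `sample_id`, `gene`,
#'   `genotype`.
#' @param template `"gDNA"` or `"cDNA"`.
#' @param triage optional [TriageReport-class] to attach.
#' @return an [AlleleCounts-class].
#' @export
tabulateCounts <- function(readTable, genotypes, template = c("cDNA", "gDNA"),
                           triage = NULL) {
  template <- match.arg(template)
  use <- readTable[readTable$allele %in% c("M", "m"), , drop = FALSE]
  excl <- data.frame(sample_id = character(), gene = character(),
                     reason = character(), stringsAsFactors = FALSE)
  if (nrow(use)) {
    agg <- stats::aggregate(cbind(count_M = use$allele == "M",
                                  count_m = use$allele == "m"),
                            by = list(sample_id = use$sample_id,
                                      gene = use$gene), FUN = sum)
  } else {
    agg <- data.frame(sample_id = character(), gene = character(),
                      count_M = integer(), count_m = integer(),
                      stringsAsFactors = FALSE)
  }
  gkey <- paste(genotypes$sample_id, genotypes$gene)
  akey <- paste(agg$sample_id, agg$gene)
  gt <- genotypes$genotype[match(akey, gkey)]
  no_gt <- is.na(gt)
  not_het <- !no_gt & gt != "Mm"
  if (any(no_gt))
    excl <- rbind(excl, data.frame(sample_id = agg$sample_id[no_gt],
                                   gene = agg$gene[no_gt],
                                   reason = "no_genotype"))
  if (any(not_het))
    excl <- rbind(excl, data.frame(sample_id = agg$sample_id[not_het],
                                   gene = agg$gene[not_het],
                                   reason = "not_heterozygous"))
  keep <- agg[!no_gt & !not_het, , drop = FALSE]
  ## heterozygous pairs never observed in the reads
  het <- genotypes[genotypes$genotype == "Mm", , drop = FALSE]
  hkey <- paste(het$sample_id, het$gene)
  unseen <- !(hkey %in% paste(keep$sample_id, keep$gene))
  if (any(unseen))
    excl <- rbind(excl, data.frame(sample_id = het$sample_id[unseen],
                                   gene = het$gene[unseen],
                                   reason = "no_usable_reads"))
  keep$template <- rep(template, nrow(keep))
  keep$count_M <- as.integer(keep$count_M)
  keep$count_m <- as.integer(keep$count_m)
  keep$single_allele_only <- (keep$count_M == 0L) != (keep$count_m == 0L)
  keep <- keep[order(keep$gene, keep$sample_id),
               c("sample_id", "gene", "template", "count_M", "count_m",
                 "single_allele_only")]
  rownames(keep) <- NULL
  new("AlleleCounts", counts = keep, triage = triage, exclusions = excl)
}

#' Count marker-SNP alleles from an indexed FASTQ run
#'
#' Full read-sorting stage: parse, demultiplex, match against the
#' amplicon library, extract the marker-SNP allele and tabulate counts,
#' with per-read triage accounting. Demultiplexing failures, reference
#' non-matches, too-short reads and flank-verification failures count as
#' `failedMatch`; matched reads not covering the marker SNP or showing a
#' base equal to neither expected allele count as `missingMsnpBase`.
#'
#' @param fastq path to a FASTQ file or a data.frame from
#'   [readIndexedFastq()].
#' @param panel an [AmpliconPanel-class].
#' @param genotypes genotype data.frame (see [readGenotypes()]).
#' @param template `"gDNA"` or `"cDNA"`.
#' @param indexMode passed to [demultiplexReads()].
#' @param minIdentity,minReadLen passed to [matchReads()].
#' @param flankLen,maxFlankMismatch passed to [extractAlleles()].
#' @return an [AlleleCounts-class] with an attached [TriageReport-class].
#' @export
countReads <- function(fastq, panel, genotypes, template = c("cDNA", "gDNA"),
                       indexMode = "exact", minIdentity = 0.9,
                       minReadLen = 30L, flankLen = 20L,
                       maxFlankMismatch = 2L) {
  template <- match.arg(template)
  reads <- if (is.character(fastq)) readIndexedFastq(fastq) else fastq
  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  hist <- table(factor(lens, levels = sort(unique(lens))))
  histv <- stats::setNames(as.integer(hist), names(hist))

  sample_id <- demultiplexReads(reads$sequence, indexMap(panel),
                                mode = indexMode)
  insert <- substr(reads$sequence, 6L, 1000000L)
  m <- matchReads(insert, buildReferenceLibrary(panel),
                  minIdentity = minIdentity, minReadLen = minReadLen)
  m$gene[is.na(sample_id)] <- NA_character_     # unassigned index
  allele <- extractAlleles(insert, m, panel, flankLen = flankLen,
                           maxFlankMismatch = maxFlankMismatch)

  failed <- is.na(m$gene) | (!is.na(allele) & allele == "flank_fail")
  missing <- !failed & allele %in% c("missing", "neither")
  usable <- !failed & !missing
  rt <- data.frame(sample_id = sample_id[usable], gene = m$gene[usable],
                   allele = allele[usable], stringsAsFactors = FALSE)
  counts <- tabulateCounts(rt, genotypes, template = template)
  cts <- countsTable(counts)
  singles <- sum(cts$count_M[cts$single_allele_only],
                 cts$count_m[cts$single_allele_only])
  triage <- new("TriageReport", totalReads = n,
                failedMatch = as.integer(sum(failed)),
                missingMsnpBase = as.integer(sum(missing)),
                singleAlleleOnly = as.integer(singles),
                usable = as.integer(sum(usable)), lengthHistogram = histv)
  initialize(counts, triage = triage)
}

#' Read or write allele-count tables
#'
#' `readCounts` loads a precomputed counts TSV (columns `sample_id`,
#' `gene`, `template`, `count_M`, `count_m`) as produced by
#' `writeCounts`, bypassing the read-sorting stage.
#'
#' @param path TSV path.
#' @param x an [AlleleCounts-class].
#' @return `readCounts`: an [AlleleCounts-class]; `writeCounts`: the
#'   path, invisibly.
#' @export
readCounts <- function(path) {
  df <- readTsv(path)
  stopifnot_cols(df, c("sample_id", "gene", "template", "count_M", "count_m"),
                 "counts table")
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  if (is.null(df$single_allele_only))
    df$single_allele_only <- (df$count_M == 0L) != (df$count_m == 0L)
  new("AlleleCounts", counts = df, triage = NULL,
      exclusions = data.frame(sample_id = character(), gene = character(),
                              reason = character(), stringsAsFactors = FALSE))
}

#' @rdname readCounts
#' @export
writeCounts <- function(x, path) writeTsv(countsTable(x), path)

#' Serialize a triage report to JSON
#'
#' @param triage a [TriageReport-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTriageJson <- function(triage, path) {
  obj <- list(total_reads = triage@totalReads,
              failed_match = triage@failedMatch,
              missing_msnp_base = triage@missingMsnpBase,
              single_allele_only = triage@singleAlleleOnly,
              usable = triage@usable,
              read_length_histogram = as.list(triage@lengthHistogram))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
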