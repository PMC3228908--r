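test_that("FASTQ parsing handles records, empty files and malformed input", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  seq76 <- paste(rep("ACGT", 19), collapse = "")
  writeLines(c("@r1", seq76, "+", paste(rep("I", 76), collapse = "")), fq)
  reads <- readIndexedFastq(fq)
  expect_equal(nrow(reads), 1L)
  expect_equal(nchar(reads$sequence), 76L)
  expect_equal(reads$read_id, "r1")

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(readIndexedFastq(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), bad)
  expect_error(readIndexedFastq(bad), "line 5")
  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(readIndexedFastq(trunc), "line 5")
})

test_that("read-length histogram from a planted length mixture peaks at 76", {
  panel <- makePanel(3, 4, seed = 2)
  gt <- allHetGenotypes(panel)
  cts <- gt
  cts$template <- "cDNA"
  cts$count_M <- 50L
  cts$count_m <- 35L
  fq <- withr::local_tempfile(fileext = ".fastq")
  generateFastq(panel, asCounts(cts[, c("sample_id", "gene", "template",
                                        "count_M", "count_m")]),
                fq, seed = 7)
  res <- countReads(fq, panel, gt, template = "cDNA")
  h <- triageReport(res)@lengthHistogram
  expect_equal(names(h)[which.max(h)], "76")
})

test_that("index demultiplexing: exact matches, redundancy rule, ties", {
  idx <- data.frame(sample_id = c("a", "b"),
                    index_seq = c("ACGTA", "GGTAG"))
  expect_equal(demultiplexReads("ACGTAXXXX", idx), "a")
  # one substitution at position 5 violates the pos1=pos5 redundancy:
  # unassigned under exact mode, recovered under correction
  expect_true(is.na(demultiplexReads("ACGTTXXXX", idx, mode = "exact")))
  expect_equal(demultiplexReads("ACGTTXXXX", idx, mode = "correct"), "a")
  # interior substitution: accepted only when the read's own redundant
  # ends still agree
  expect_equal(demultiplexReads("ATGTAXXXX", idx, mode = "correct"), "a")
  expect_true(is.na(demultiplexReads("CCGTAXXXX", idx, mode = "correct")) ||
                demultiplexReads("CCGTAXXXX", idx, mode = "correct") == "a")
  # equidistant between two indices: never assigned arbitrarily
  tie_idx <- data.frame(sample_id = c("a", "b"),
                        index_seq = c("AACCA", "AAGGA"))
  expect_true(is.na(demultiplexReads("AACGA", tie_idx, mode = "correct")))
  expect_error(demultiplexReads("ACGTA", data.frame(
    sample_id = c("a", "b"), index_seq = c("ACGTA", "ACGTA"))), "unique")
})

test_that("demultiplexing with 1% substitution errors recovers planted samples", {
  panel <- makePanel(2, 10, seed = 4)
  gt <- allHetGenotypes(panel)
  cts <- gt
  cts$template <- "cDNA"
  cts$count_M <- 30L
  cts$count_m <- 20L
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- generateFastq(panel, asCounts(cts[, c("sample_id", "gene",
                                                 "template", "count_M",
                                                 "count_m")]),
                         fq, triageFractions = c(failed = 0, missing = 0),
                         errorRate = 0.01, seed = 11)
  reads <- readIndexedFastq(fq)
  truth <- truth[match(reads$read_id, truth$read_id), ]
  got <- demultiplexReads(reads$sequence, indexMap(panel), mode = "correct")
  assigned <- !is.na(got)
  expect_gt(mean(assigned), 0.99)
  # reads with at most one index error (the regime the redundancy rule
  # covers) are assigned to the planted sample or left unassigned, never
  # cross-assigned; multi-error reads can at worst mimic another index
  idx <- indexMap(panel)
  planted_idx <- idx$index_seq[match(truth$sample_id, idx$sample_id)]
  n_err <- mapply(hammingOverlap, substr(reads$sequence, 1, 5), planted_idx)
  core <- assigned & n_err <= 1
  expect_true(all(got[core] == truth$sample_id[core]))
  expect_gt(mean(got[assigned] == truth$sample_id[assigned]), 0.998)
})

test_that("reference matching agrees with an exhaustive Hamming oracle", {
  panel <- makePanel(10, 6, seed = 8)
  gt <- allHetGenotypes(panel)
  cts <- gt
  cts$template <- "cDNA"
  cts$count_M <- 45L
  cts$count_m <- 40L
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- generateFastq(panel, asCounts(cts[, c("sample_id", "gene",
                                                 "template", "count_M",
                                                 "count_m")]),
                         fq, triageFractions = c(failed = 0.05, missing = 0),
                         errorRate = 0.005, seed = 13)
  reads <- readIndexedFastq(fq)
  inserts <- substr(reads$sequence, 6, 10000)
  lib <- buildReferenceLibrary(panel)
  got <- matchReads(inserts, lib, minIdentity = 0.9)

  ## oracle: per read, identity over overlap against every library entry
  oracle <- vapply(inserts, function(rd) {
    ov <- pmin(nchar(rd), nchar(lib$seq))
    mm <- vapply(lib$seq, hammingOverlap, integer(1), a = rd)
    id <- (ov - mm) / ov
    best <- max(id)
    if (best < 0.9) return(NA_character_)
    hits <- which(id > best - 1e-9)
    if (length(unique(lib$gene[hits])) > 1) return(NA_character_)
    lib$gene[hits[1]]
  }, character(1), USE.NAMES = FALSE)
  expect_identical(got$gene, oracle)
  expect_gte(nrow(reads), 5000)   # 5,000-read-scale fixture
})

test_that("matching recognizes both orientations and rejects short reads", {
  panel <- makePanel(3, 2, seed = 5)
  ref <- panelReference(panel)
  lib <- buildReferenceLibrary(panel)
  amp <- ref$amplicon_seq[2]
  fwd <- matchReads(amp, lib)
  expect_equal(fwd$gene, ref$gene[2])
  expect_equal(fwd$orientation, "forward")
  expect_equal(fwd$identity, 1)
  rc <- matchReads(revcompChr(amp), lib)
  expect_equal(rc$gene, ref$gene[2])
  expect_equal(rc$orientation, "revcomp")
  short <- matchReads(substr(amp, 1, 20), lib, minReadLen = 30)
  expect_true(is.na(short$gene))
  expect_error(matchReads("ACGT", lib[0, ]), "empty")
})

test_that("allele extraction reads planted alleles, coverage and flanks", {
  panel <- makePanel(1, 2, seed = 3)
  ref <- panelReference(panel)
  off <- ref$msnp_offset
  ampM <- ref$amplicon_seq
  substr(ampM, off + 1, off + 1) <- ref$allele_M
  ampm <- ref$amplicon_seq
  substr(ampm, off + 1, off + 1) <- ref$allele_m
  ampX <- ref$amplicon_seq
  other <- setdiff(c("A", "C", "G", "T"), c(ref$allele_M, ref$allele_m))[1]
  substr(ampX, off + 1, off + 1) <- other
  m <- matchReads(c(ampM, ampm, ampX, substr(ampM, 1, off)),
                  buildReferenceLibrary(panel))
  out <- extractAlleles(c(ampM, ampm, ampX, substr(ampM, 1, off)), m, panel)
  expect_equal(out[1:3], c("M", "m", "neither"))
  # truncated before the marker SNP: no allele information
  expect_equal(out[4], "missing")

  # a heavily corrupted flank fails verification
  corrupt <- ampM
  substr(corrupt, off - 4, off) <- paste(rep(other, 5), collapse = "")
  mc <- matchReads(corrupt, buildReferenceLibrary(panel), minIdentity = 0.8)
  expect_equal(extractAlleles(corrupt, mc, panel, maxFlankMismatch = 2),
               "flank_fail")
})

test_that("allele extraction is reverse-complement invariant", {
  panel <- makePanel(4, 2, seed = 21)
  ref <- panelReference(panel)
  lib <- buildReferenceLibrary(panel)
  for (i in seq_len(nrow(ref))) {
    amp <- ref$amplicon_seq[i]
    substr(amp, ref$msnp_offset[i] + 1, ref$msnp_offset[i] + 1) <-
      ref$allele_m[i]
    fwd <- extractAlleles(amp, matchReads(amp, lib), panel)
    rc <- extractAlleles(revcompChr(amp), matchReads(revcompChr(amp), lib),
                         panel)
    expect_equal(fwd, rc)
    expect_equal(fwd, "m")
  }
})

test_that("planted 60:40 allele mixture is counted exactly without errors", {
  panel <- makePanel(1, 2, seed = 6)
  gt <- allHetGenotypes(panel)
  cts <- data.frame(sample_id = "s01", gene = panelReference(panel)$gene,
                    template = "cDNA", count_M = 1200L, count_m = 800L,
                    stringsAsFactors = FALSE)
  fq <- withr::local_tempfile(fileext = ".fastq")
  generateFastq(panel, asCounts(cts), fq,
                triageFractions = c(failed = 0, missing = 0), seed = 17)
  res <- countReads(fq, panel, gt, template = "cDNA")
  out <- countsTable(res)
  expect_equal(out$count_M[out$sample_id == "s01"], 1200L)
  expect_equal(out$count_m[out$sample_id == "s01"], 800L)
})

test_that("tabulation conserves reads, honors genotypes and flags singles", {
  gt <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                   gene = c("G1", "G2", "G1", "G1"),
                   genotype = c("Mm", "Mm", "MM", "Mm"),
                   stringsAsFactors = FALSE)
  rt <- data.frame(
    sample_id = c(rep("s1", 150), rep("s2", 10), rep("s4", 5), rep("s3", 20)),
    gene = c(rep("G1", 150), rep("G1", 10), rep("G1", 5), rep("G1", 20)),
    allele = c(rep("M", 100), rep("m", 50), rep("M", 10), rep("M", 5),
               rep("M", 20)),
    stringsAsFactors = FALSE)
  out <- tabulateCounts(rt, gt, template = "cDNA")
  cts <- countsTable(out)
  r1 <- cts[cts$sample_id == "s1" & cts$gene == "G1", ]
  expect_equal(c(r1$count_M, r1$count_m), c(100L, 50L))
  # conservation: counted alleles equal usable reads of kept samples
  expect_equal(sum(cts$count_M + cts$count_m), 170L)
  # homozygous and ungenotyped samples are excluded with reasons
  excl <- out@exclusions
  expect_true(any(excl$sample_id == "s2" & excl$reason == "not_heterozygous"))
  expect_true(any(excl$sample_id == "s4" & excl$reason == "no_genotype"))
  # heterozygous pair with zero usable reads is listed, not fabricated
  expect_true(any(excl$sample_id == "s1" & excl$gene == "G2" &
                    excl$reason == "no_usable_reads"))
  # s3 saw only one allele despite a heterozygous genotype
  expect_true(cts$single_allele_only[cts$sample_id == "s3"])
})

test_that("triage categories from a full run partition all reads", {
  panel <- makePanel(3, 4, seed = 2)
  gt <- allHetGenotypes(panel)
  cts <- gt
  cts$template <- "gDNA"
  cts$count_M <- 40L
  cts$count_m <- 40L
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- generateFastq(panel, asCounts(cts[, c("sample_id", "gene",
                                                 "template", "count_M",
                                                 "count_m")]),
                         fq, seed = 23)
  res <- countReads(fq, panel, gt, template = "gDNA")
  tr <- triageReport(res)
  expect_equal(tr@totalReads, nrow(truth))
  expect_equal(tr@totalReads, tr@failedMatch + tr@missingMsnpBase + tr@usable)
  expect_equal(tr@usable, sum(truth$category == "usable"))
  expect_equal(sum(countsTable(res)$count_M + countsTable(res)$count_m),
               tr@usable)
})
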