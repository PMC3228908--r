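## Shared fixture builders. All fixtures are generated in code under
## fixed seeds; nothing is read from disk.

## minimal panel: nGenes random amplicons, nSamples indexed samples
makePanel <- function(nGenes = 3L, nSamples = 4L, seed = 2L) {
  generatePanel(nGenes, sprintf("s%02d", seq_len(nSamples)), seed = seed)
}

## all-heterozygous genotype table for a panel
allHetGenotypes <- function(panel) {
  ref <- panelReference(panel)
  idx <- indexMap(panel)
  gt <- expand.grid(sample_id = idx$sample_id, gene = ref$gene,
                    stringsAsFactors = FALSE)
  gt$genotype <- "Mm"
  gt
}

## AlleleCounts object from a plain data.frame of planted counts
asCounts <- function(df) {
  df$single_allele_only <- (df$count_M == 0L) != (df$count_m == 0L)
  new("AlleleCounts", counts = df, triage = NULL,
      exclusions = data.frame(sample_id = character(), gene = character(),
                              reason = character(), stringsAsFactors = FALSE))
}

## uncorrected AEITable straight from per-record linear ratios
asAEI <- function(sample_id, gene, template, ratio, total_reads = 1000L,
                  corrected = FALSE) {
  rec <- data.frame(sample_id = sample_id, gene = gene, template = template,
                    ratio = ratio, log2_ratio = log2(ratio),
                    total_reads = total_reads, corrected = corrected,
                    stringsAsFactors = FALSE)
  new("AEITable", records = rec,
      exclusions = data.frame(sample_id = character(), gene = character(),
                              template = character(), reason = character(),
                              stringsAsFactors = FALSE))
}

## brute-force mismatch count between two strings over their overlap
hammingOverlap <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  sum(ca[seq_len(n)] != cb[seq_len(n)])
}

revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
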