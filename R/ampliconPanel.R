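#' Construct an AmpliconPanel
#'
#' @param reference data.frame (or path handled by
#'   [readAmpliconReference()]) with columns `gene`, `amplicon_seq`,
#'   `msnp_offset` (0-based position of the marker SNP within the
#'   amplicon), `allele_M`, `allele_m`, `numerator_allele`.
#' @param indexMap data.frame with columns `sample_id`, `index_seq`
#'   (5-base indices whose first and fifth base coincide).
#' @return an [AmpliconPanel-class].
#' @examples
#' ref <- data.frame(gene = "G1",
#'   amplicon_seq = paste(rep("ACGT", 18), collapse = ""),
#'   msnp_offset = 36L, allele_M = "A", allele_m = "G",
#'   numerator_allele = "M")
#' idx <- data.frame(sample_id = "s1", index_seq = "ACGTA")
#' AmpliconPanel(ref, idx)
#' @export
AmpliconPanel <- function(reference, indexMap) {
  reference$gene <- as.character(reference$gene)
  reference$amplicon_seq <- toupper(as.character(reference$amplicon_seq))
  reference$msnp_offset <- as.integer(reference$msnp_offset)
  reference$allele_M <- toupper(as.character(reference$allele_M))
  reference$allele_m <- toupper(as.character(reference$allele_m))
  reference$numerator_allele <- as.character(reference$numerator_allele)
  indexMap$sample_id <- as.character(indexMap$sample_id)
  indexMap$index_seq <- toupper(as.character(indexMap$index_seq))
  new("AmpliconPanel", reference = reference, indexMap = indexMap)
}

#' Read panel tables from TSV files
#'
#' `readAmpliconReference` reads the gene reference table,
#' `readIndexMap` the sample-to-index map and `readGenotypes` the
#' per-sample marker-SNP genotypes (`MM`, `Mm` or `mm`; `Mm` marks the
#' heterozygotes on which AEI can be measured).
#'
#' @param path path to a tab-separated file.
#' @return a data.frame.
#' @export
readAmpliconReference <- function(path) {
  ref <- readTsv(path)
  stopifnot_cols(ref, c("gene", "amplicon_seq", "msnp_offset", "allele_M",
                        "allele_m", "numerator_allele"), "reference table")
  ref
}

#' @rdname readAmpliconReference
#' @export
readIndexMap <- function(path) {
  idx <- readTsv(path)
  stopifnot_cols(idx, c("sample_id", "index_seq"), "index map")
  idx
}

#' @rdname readAmpliconReference
#' @export
readGenotypes <- function(path) {
  gt <- readTsv(path)
  stopifnot_cols(gt, c("sample_id", "gene", "genotype"), "genotype table")
  bad <- setdiff(unique(gt$genotype), c("MM", "Mm", "mm"))
  if (length(bad))
    stop("genotypes must be MM, Mm or mm; found: ", paste(bad, collapse = ", "))
  gt
}

#' Expand a panel into the full read-matching reference library
#'
#' Every candidate read context is one amplicon in one of two insert
#' orientations; the library therefore holds `n_genes x 2` sequences
#' (sample assignment is handled separately by index demultiplexing, so
#' indices do not multiply the library here).
#'
#' @param panel an [AmpliconPanel-class].
#' @return data.frame with columns `gene`, `orientation` (`"forward"` or
#'   `"revcomp"`) and `seq`.
#' @export
buildReferenceLibrary <- function(panel) {
  ref <- panelReference(panel)
  fwd <- data.frame(gene = ref$gene, orientation = "forward",
                    seq = ref$amplicon_seq, stringsAsFactors = FALSE)
  rc <- data.frame(gene = ref$gene, orientation = "revcomp",
                   seq = as.character(Biostrings::reverseComplement(
                     Biostrings::DNAStringSet(ref$amplicon_seq))),
                   stringsAsFactors = FALSE)
  rbind(fwd, rc)
}
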