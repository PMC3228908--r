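## Synthetic-data generators emulating the assay's study design:
## a cohort of 52 samples, ~70 candidate genes measured only in
## marker-SNP heterozygotes (3-36 per gene), per-gene read depths of
## roughly 1,000-75,000, allele-specific PCR amplification bias up to
## ~1.5-fold, and indexed single-end reads with planted triage
## categories. Every observable is traceable to a truth table.

#' Generate a 5-bp sample index set
#'
#' Random indices over A/C/G/T with identical bases at positions 1 and
#' 5 (the redundancy that makes end-position sequencing errors
#' recognizable) and a minimum pairwise Hamming distance. With
#' `minDist = 3` single substitutions can never convert one index into
#' another's neighborhood; the mirrored-end design caps such sets at 16,
#' so larger runs default to distance 2.
#'
#' @param n number of indices.
#' @param seed integer seed.
#' @param minDist minimum pairwise Hamming distance (default 3 when
#'   `n <= 16`, else 2).
#' @return character vector of `n` index sequences.
#' @export
generateIndices <- function(n, seed = 1L, minDist = if (n <= 16) 3L else 2L) {
  bases <- c("A", "C", "G", "T")
  cand <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                      stringsAsFactors = FALSE)
  cand <- paste0(cand$b1, cand$b2, cand$b3, cand$b4, cand$b1)
  withSeed(seed, cand <- sample(cand))
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  chosen <- character(0)
  for (x in cand) {
    if (all(vapply(chosen, hamming, integer(1), a = x) >= minDist)) {
      chosen <- c(chosen, x)
      if (length(chosen) == n) return(chosen)
    }
  }
  stop("could not build ", n, " indices at pairwise distance >= ", minDist)
}

#' Generate a synthetic amplicon panel
#'
#' Random amplicons of 66-100 bp with the marker SNP at the center
#' (mirroring a design in which 76-bp reads from either end always
#' cover the SNP), random distinct M/m alleles, numerator allele M, and
#' a generated index set for the given samples.
#'
#' @param nGenes number of genes.
#' @param sampleIds character vector of sample ids.
#' @param seed integer seed.
#' @return an [AmpliconPanel-class].
#' @export
generatePanel <- function(nGenes, sampleIds, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    len <- sample(66:100, nGenes, replace = TRUE)
    seqs <- vapply(len, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
    offset <- len %/% 2L                      # 0-based, central
    alleles <- t(vapply(seq_len(nGenes), function(i) sample(bases, 2),
                        character(2)))
    ## plant the M allele at the marker position
    substr(seqs, offset + 1L, offset + 1L) <- alleles[, 1]
    ref <- data.frame(gene = sprintf("G%03d", seq_len(nGenes)),
                      amplicon_seq = seqs, msnp_offset = offset,
                      allele_M = alleles[, 1], allele_m = alleles[, 2],
                      numerator_allele = "M", stringsAsFactors = FALSE)
    idx <- data.frame(sample_id = sampleIds,
                      index_seq = generateIndices(length(sampleIds),
                                                  seed = seed + 1L))
    AmpliconPanel(ref, idx)
  })
}

#' Generate a Hardy-Weinberg cohort at one marker SNP
#'
#' Genotypes are drawn with HWE probabilities (p^2, 2pq, q^2) under
#' random mating.
#'
#' @param n cohort size.
#' @param markerFreq M-allele frequency in (0,1).
#' @param seed integer seed.
#' @param sampleIds optional ids (default `s01`, `s02`, ...).
#' @return data.frame with columns `sample_id`, `genotype`.
#' @export
generateCohort <- function(n, markerFreq, seed = 1L, sampleIds = NULL) {
  if (markerFreq <= 0 || markerFreq >= 1)
    stop("markerFreq must lie strictly in (0, 1)")
  p <- markerFreq
  ids <- sampleIds %||% sprintf("s%02d", seq_len(n))
  gt <- withSeed(seed,
    sample(c("MM", "Mm", "mm"), n, replace = TRUE,
           prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)))
  data.frame(sample_id = ids, genotype = gt, stringsAsFactors = FALSE)
}

#' Generate allele counts under amplification bias
#'
#' Read counts are binomial draws: for gDNA templates the M-allele
#' probability is `b / (1 + b)` (a heterozygote's gDNA carries the
#' alleles 1:1, so only the bias `b` displaces it); for cDNA it is
#' `b r / (1 + b r)` with `r` the true M:m expression ratio.
#'
#' @param trueRatio true M:m expression ratio `r` (> 0); ignored for
#'   gDNA.
#' @param bias allele-specific amplification bias `b` (> 0).
#' @param depth total read depth N (>= 1). Vectorized over records.
#' @param template `"gDNA"` or `"cDNA"`.
#' @param seed optional integer seed.
#' @return data.frame with columns `count_M`, `count_m`.
#' @export
generateCounts <- function(trueRatio, bias, depth,
                           template = c("cDNA", "gDNA"), seed = NULL) {
  template <- match.arg(template)
  if (any(trueRatio <= 0) || any(bias <= 0)) stop("r and b must be positive")
  if (any(depth < 1)) stop("depth must be at least 1")
  p <- if (template == "gDNA") bias / (1 + bias)
       else bias * trueRatio / (1 + bias * trueRatio)
  n <- max(length(trueRatio), length(bias), length(depth))
  depth <- rep_len(depth, n); p <- rep_len(p, n)
  cM <- withSeed(seed, stats::rbinom(n, depth, p))
  data.frame(count_M = cM, count_m = as.integer(depth) - cM)
}

#' Define a synthetic study design
#'
#' The default (`profile = "published"`) emulates the assay's study
#' conditions: 52 samples; 70 genes of which 42 carry a strong,
#' fully marker-linked regulatory variant (effects 0.6-1.2 log2 units,
#' common marker), 20 carry a more modest variant at a low-frequency
#' marker (few heterozygotes), and 8 are null; per-gene amplification
#' bias in [0.67, 1.5]; read depths log-uniform over 1,079-33,250
#' (gDNA) and 1,277-75,440 (cDNA). `profile = "null"` sets every
#' effect to zero (error-calibration runs). Fully linked variants use
#' `P = markerFreq` so that every heterozygote carries the regulatory
#' heterozygosity in the same phase.
#'
#' @param profile `"published"` or `"null"`.
#' @param nSamples cohort size (default 52).
#' @param seed integer seed controlling the per-gene parameter draws.
#' @param genes optional data.frame overriding the gene table entirely
#'   (columns `name`, `marker_freq`, `bias`, `rvar_P`, `rvar_effect`,
#'   `rvar_dprime`).
#' @return a list of class `study_design` with elements `n_samples`,
#'   `genes`, `depth_gdna`, `depth_cdna`, `seed`.
#' @export
studyDesign <- function(profile = c("published", "null"), nSamples = 52L,
                        seed = 1L, genes = NULL) {
  profile <- match.arg(profile)
  if (is.null(genes)) {
    genes <- withSeed(seed, {
      n_strong <- 42L; n_weak <- 20L; n_null <- 8L
      mf <- c(stats::runif(n_strong, 0.2, 0.5),
              stats::runif(n_weak, 0.05, 0.09),
              stats::runif(n_null, 0.2, 0.5))
      eff <- c(stats::runif(n_strong, 0.6, 1.2),
               stats::runif(n_weak, 0.4, 0.6),
               rep(0, n_null))
      if (profile == "null") eff[] <- 0
      data.frame(name = sprintf("G%03d", seq_len(n_strong + n_weak + n_null)),
                 marker_freq = mf, bias = stats::runif(70, 0.67, 1.5),
                 rvar_P = mf, rvar_effect = eff,
                 rvar_dprime = ifelse(eff > 0, 1, 0),
                 stringsAsFactors = FALSE)
    })
  }
  structure(list(n_samples = as.integer(nSamples), genes = genes,
                 depth_gdna = c(1079, 33250), depth_cdna = c(1277, 75440),
                 seed = as.integer(seed)),
            class = "study_design")
}

logUniform <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a full synthetic study
#'
#' For every gene, draws a Hardy-Weinberg cohort at its marker SNP,
#' assigns each heterozygote a true log2 AEI from the gene's
#' single-variant regulatory model, and generates biased binomial gDNA
#' and cDNA allele counts at log-uniform read depths. True ratios are
#' expressed with the M allele in the numerator.
#'
#' @param design a design from [studyDesign()].
#' @return list with `counts` (an [AlleleCounts-class] holding both
#'   templates), `genotypes` (long data.frame over genes), `truth`
#'   (per heterozygote sample x gene: true log2 ratio, bias, depths and
#'   planted counts), and `reference` (gene/numerator table for
#'   [computeAEI()]).
#' @export
generateStudy <- function(design = studyDesign()) {
  genes <- design$genes
  seeds <- childSeeds(design$seed, nrow(genes) * 4L + 1L)
  gt_all <- list(); truth_all <- list(); cts_all <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s0 <- seeds[(i - 1L) * 4L + 1L]
    cohort <- generateCohort(design$n_samples, g$marker_freq, seed = s0)
    gt_all[[i]] <- data.frame(sample_id = cohort$sample_id, gene = g$name,
                              genotype = cohort$genotype,
                              stringsAsFactors = FALSE)
    het <- cohort$sample_id[cohort$genotype == "Mm"]
    if (!length(het)) next
    nh <- length(het)
    s <- if (g$rvar_effect == 0) rep(0L, nh) else {
      pr <- phaseProbsK1(g$rvar_P, g$marker_freq, g$rvar_dprime)
      withSeed(seeds[(i - 1L) * 4L + 2L],
               sample(c(1L, -1L, 0L), nh, replace = TRUE, prob = pr))
    }
    true_log2 <- g$rvar_effect * s
    depths <- withSeed(seeds[(i - 1L) * 4L + 3L], {
      data.frame(gdna = round(logUniform(nh, design$depth_gdna)),
                 cdna = round(logUniform(nh, design$depth_cdna)))
    })
    cg <- generateCounts(1, g$bias, depths$gdna, "gDNA",
                         seed = seeds[(i - 1L) * 4L + 4L])
    cc <- generateCounts(2^true_log2, g$bias, depths$cdna, "cDNA",
                         seed = seeds[(i - 1L) * 4L + 4L] + 1L)
    truth_all[[i]] <- data.frame(sample_id = het, gene = g$name,
                                 true_log2 = true_log2, bias = g$bias,
                                 depth_gdna = depths$gdna,
                                 depth_cdna = depths$cdna,
                                 stringsAsFactors = FALSE)
    cts_all[[i]] <- rbind(
      data.frame(sample_id = het, gene = g$name, template = "gDNA",
                 count_M = cg$count_M, count_m = cg$count_m,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = het, gene = g$name, template = "cDNA",
                 count_M = cc$count_M, count_m = cc$count_m,
                 stringsAsFactors = FALSE))
  }
  cts <- do.call(rbind, cts_all)
  cts$single_allele_only <- (cts$count_M == 0L) != (cts$count_m == 0L)
  rownames(cts) <- NULL
  list(counts = new("AlleleCounts", counts = cts, triage = NULL,
                    exclusions = data.frame(sample_id = character(),
                                            gene = character(),
                                            reason = character())),
       genotypes = do.call(rbind, gt_all),
       truth = do.call(rbind, truth_all),
       reference = data.frame(gene = genes$name, numerator_allele = "M",
                              stringsAsFactors = FALSE))
}

#' Generate an indexed FASTQ run with planted triage categories
#'
#' Emits one read per planted allele count (index + amplicon insert in
#' a random orientation), then adds reads in the planted triage
#' categories: unmatchable reads (random inserts that fail reference
#' matching) and reads truncated before the marker SNP. A planted
#' fraction of the usable reads is full length (76 bp by default), the
#' rest are shortened but still cover the marker SNP. Substitution
#' errors are applied at `errorRate` per base across the whole read.
#' Category counts are planted deterministically (rounded from the
#' fractions), so the expected triage report is exact up to rounding.
#'
#' @param panel an [AmpliconPanel-class].
#' @param counts an [AlleleCounts-class] (single template) giving the
#'   planted usable-read counts per sample/gene.
#' @param path output FASTQ path.
#' @param triageFractions named vector with `failed` and `missing`
#'   fractions of total reads (default `c(failed = 0.30,
#'   missing = 0.03)`).
#' @param fullLengthFrac fraction of usable reads at full read length
#'   (default 0.85).
#' @param readLen full read length including the 5-bp index
#'   (default 76).
#' @param errorRate per-base substitution rate (default 0).
#' @param seed integer seed.
#' @return invisibly, a truth data.frame with one row per read
#'   (`read_id`, `category`, `sample_id`, `gene`, `allele`,
#'   `orientation`, `length`).
#' @export
generateFastq <- function(panel, counts, path,
                          triageFractions = c(failed = 0.30, missing = 0.03),
                          fullLengthFrac = 0.85, readLen = 76L,
                          errorRate = 0, seed = 1L) {
  ref <- panelReference(panel)
  idx <- indexMap(panel)
  cts <- countsTable(counts)
  if (!all(cts$gene %in% ref$gene)) stop("counts contain genes not in panel")
  if (!all(cts$sample_id %in% idx$sample_id))
    stop("counts contain samples not in the index map")
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    ## --- usable reads, one per planted allele count
    per <- cts[rep(seq_len(nrow(cts)),
                   times = cts$count_M + cts$count_m), ,
               drop = FALSE]
    allele <- unlist(mapply(function(M, m) c(rep("M", M), rep("m", m)),
                            cts$count_M, cts$count_m, SIMPLIFY = FALSE))
    nU <- nrow(per)
    r <- ref[match(per$gene, ref$gene), ]
    ampL <- nchar(r$amplicon_seq)
    ori <- sample(c("forward", "revcomp"), nU, replace = TRUE)
    full_insert <- pmin(readLen - 5L, ampL)
    is_full <- seq_len(nU) %in% sample.int(nU, round(fullLengthFrac * nU))
    ## shortened reads must still reach the marker SNP in their orientation
    cover_need <- ifelse(ori == "forward", r$msnp_offset + 1L,
                         ampL - r$msnp_offset)
    lo <- pmax(30L, cover_need)
    short_insert <- lo + floor(stats::runif(nU) *
                                 pmax(1L, full_insert - lo))
    insert_len <- ifelse(is_full, full_insert, pmin(short_insert,
                                                    full_insert))
    ## plant the allele base and cut the insert
    amp <- r$amplicon_seq
    ab <- ifelse(allele == "M", r$allele_M, r$allele_m)
    substr(amp, r$msnp_offset + 1L, r$msnp_offset + 1L) <- ab
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(amp)))
    insert <- ifelse(ori == "forward", substr(amp, 1L, insert_len),
                     substr(rc, 1L, insert_len))
    useq <- paste0(idx$index_seq[match(per$sample_id, idx$sample_id)],
                   insert)
    usable <- data.frame(category = "usable", sample_id = per$sample_id,
                         gene = per$gene, allele = allele,
                         orientation = ori, sequence = useq,
                         stringsAsFactors = FALSE)

    ## --- planted triage categories, counts exact by construction
    fracU <- 1 - sum(triageFractions)
    nFail <- round(nU * triageFractions[["failed"]] / fracU)
    nMiss <- round(nU * triageFractions[["missing"]] / fracU)
    failseq <- vapply(seq_len(nFail), function(i)
      paste0(sample(idx$index_seq, 1L),
             paste(sample(bases, readLen - 5L, replace = TRUE),
                   collapse = "")), character(1))
    failed <- data.frame(category = rep("failed", nFail),
                         sample_id = rep(NA_character_, nFail),
                         gene = rep(NA_character_, nFail),
                         allele = rep(NA_character_, nFail),
                         orientation = rep("forward", nFail),
                         sequence = failseq, stringsAsFactors = FALSE)
    mi <- sample.int(nrow(cts), nMiss, replace = TRUE)
    mg <- ref[match(cts$gene[mi], ref$gene), ]
    mlen <- 30L + floor(stats::runif(nMiss) * pmax(1L, mg$msnp_offset - 30L))
    missseq <- paste0(idx$index_seq[match(cts$sample_id[mi],
                                          idx$sample_id)],
                      substr(mg$amplicon_seq, 1L, mlen))
    missing <- data.frame(category = rep("missing", nMiss),
                          sample_id = cts$sample_id[mi],
                          gene = cts$gene[mi],
                          allele = rep(NA_character_, nMiss),
                          orientation = rep("forward", nMiss),
                          sequence = missseq, stringsAsFactors = FALSE)
    truth <- rbind(usable, failed, missing)
    truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
    truth$read_id <- sprintf("read%06d", seq_len(nrow(truth)))
    truth$length <- nchar(truth$sequence)

    if (errorRate > 0) {
      truth$sequence <- vapply(truth$sequence, function(sq) {
        ch <- strsplit(sq, "")[[1]]
        hit <- stats::runif(length(ch)) < errorRate
        if (any(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    qual <- vapply(truth$length, function(L)
      paste(rep("I", L), collapse = ""), character(1))
    writeLines(paste0("@", truth$read_id, "\n", truth$sequence, "\n+\n",
                      qual), path)
    invisible(truth[, c("read_id", "category", "sample_id", "gene",
                        "allele", "orientation", "length")])
  })
}
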