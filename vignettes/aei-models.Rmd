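---
title: "Measuring and modeling allelic expression imbalance with aeiscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling allelic expression imbalance with aeiscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeiscope)
```

## The measurement

Allelic expression imbalance (AEI) compares the two copies of a gene
*within* one individual. A transcribed marker SNP (mSNP) with alleles M
and m distinguishes the two mRNA pools in a heterozygote; the AEI ratio
is the amount of transcript carrying one allele divided by the amount
carrying the other, with the per-gene numerator/denominator assignment
fixed in the amplicon reference table. Because each allele controls for
the other, sample-to-sample variation in RNA quality, cell composition
and trans-acting environment largely cancels — the property that makes
AEI far more sensitive than between-sample expression comparisons. We
work on the log2 scale, where over- and under-expression are symmetric
about 0.

The assay design this package implements is PCR/sequencing based: short
amplicons (66–100 bp, mSNP near the center) are amplified per sample
from genomic DNA (gDNA) and cDNA of mSNP heterozygotes, ligated to 5-bp
sample indices, pooled, and sequenced as single-end reads. `countReads()`
performs the read sorting: index demultiplexing, ungapped-identity
matching against the amplicon library in both insert orientations,
orientation-normalized extraction of the mSNP base with verification of
up to 20 bp of flanking sequence on each side, and tabulation into
per-(sample, gene, template) allele counts with full triage accounting.

Design choices in this stage, and why:

* **Ungapped identity instead of an external aligner.** Amplicons are
  short, indels are not part of the error model, and a deterministic
  matcher is exactly testable against an exhaustive Hamming-distance
  oracle. The identity threshold (default 0.9 over the aligned overlap)
  and the per-flank mismatch allowance (default 2 per 20 bp) are
  configurable; reads shorter than 30 bases after the index are never
  matched.
* **Index redundancy.** Indices carry identical bases at positions 1
  and 5. In the default exact mode any index mismatch discards the
  read. In `"correct"` mode one substitution is tolerated when the
  redundant ends still identify the index: an end-position error leaves
  the other copy intact, and an interior error is accepted only when
  the read's own positions 1 and 5 agree. Ties between indices are
  never resolved arbitrarily. Note that no single-error-correcting rule
  can exclude cross-assignment when *two* errors mimic another index;
  the synthetic index generator therefore enforces a minimum pairwise
  Hamming distance (3 for up to 16 samples, 2 beyond — the mirrored-end
  design admits at most 16 distance-3 indices).
* **Coordinates are 0-based** for the mSNP offset within the amplicon.
* **Qualities are parsed but unused**; the only gate is read length.
* **Triage partition.** Every read lands in exactly one of: failed
  match (unassignable index, no reference match, too short, or failed
  flank verification), missing mSNP base (matched but not covering the
  mSNP, or showing a base that is neither expected allele), or usable.
  Usable reads in gene/sample pairs where only one allele was ever seen
  despite a heterozygous genotype are flagged `single_allele_only` — a
  genotype-discordance signal, not a fourth category.

## Correction for amplification bias

Genomic DNA of a heterozygote carries the two alleles 1:1, so any
departure of gDNA ratios from 1 measures allele-specific PCR
amplification bias (observed up to ~1.5-fold). `fitCorrectionFactors()`
computes, per gene, the inverse of the arithmetic mean of the
uncorrected gDNA linear ratios; `applyCorrection()` multiplies every
gDNA and cDNA ratio by it, making each gene's mean corrected gDNA ratio
exactly 1. The arithmetic mean follows the assay's published procedure;
a geometric-mean option is provided because it is the log2-symmetric
alternative — under it (and only under it) swapping the numerator
allele exactly mirrors all downstream summaries. Records with a zero
allele count cannot form a ratio and are excluded with a reason rather
than pseudocounted (a `pseudocount = 0.5` option exists but is off by
default). No gDNA outliers are excluded before averaging.

## Measurement error

Two estimators, both driven by the corrected gDNA ratios:

1. **Distribution statistics** (`gdnaDistributionStats()`): mean, SD,
   SEM and the empirical central 95% interval (2.5/97.5 percentiles) of
   the normalized gDNA ratios. The conventional significance threshold
   of ±0.29 log2 units (linear 0.82–1.22) is the band containing 95% of
   gDNA control ratios at study scale; `callSignificance()` applies it
   with strict inequalities.
2. **The rectangle method** (`rectangleErrorEstimate()`,
   `buildErrorCurve()`): for a read-count threshold X, the bound E such
   that a chosen fraction (95% or 99%) of |log2 gDNA ratio| values with
   more than X reads lies within ±E. Geometrically this is the smallest
   symmetric rectangle containing that fraction of the points; it is
   implemented as the order statistic at rank `ceiling(conf * n)`,
   which is identical, deterministic and oracle-testable. The curve
   over a grid of X (default 500–50,000, including the anchors 1,000,
   13,500 and 24,300) is forced monotone non-increasing by isotonic
   regression, since sampling noise can invert adjacent thresholds.

The theoretical floor is the binomial envelope
(`binomialEnvelope()`): with both alleles at frequency 0.5, the
M-count is Binomial(N, 0.5) and the envelope is the log2 ratio at the
exact binomial quantiles, converging to half-width
$z_{\alpha/2}\,2/(\ln 2\sqrt{N})$ by the delta method. Real gDNA
spreads are wider than this envelope — the extra-binomial component is
what the rectangle method captures.

Two numerical caveats worth knowing. Read depths below the smallest
curve threshold return the largest (most conservative) bound with a
warning. And per-record depth-adaptive calls run somewhat above the
nominal 5% false-positive rate on null data (~10% in our simulations),
because each depth stratum is noisier than the pooled deeper tail that
set its bound; the containment property is exact per threshold, not per
record.

## Modeling log2AEI population distributions

Ordered per-gene distributions of log2AEI across heterozygotes carry a
reproducible shape — uniphasic (all significant ratios one sign),
skewed, or biphasic — and the package's population-genetic model
explains these shapes from the gene's cis-regulatory architecture. A
`RegulatoryModel` holds the marker frequency P(M), up to four
regulatory variants (high-expression-allele frequency P, additive log2
effect, D′ to the marker, optional pairwise D′), and a Gaussian noise
SD.

* `haplotypeFreqs()` is the standard two-locus decomposition with D′
  scaled by its frequency-constrained maximum.
* `buildJoint()` enumerates all `2^(k+1)` haplotypes exactly. The joint
  reproduces every marginal and every variant–marker D′; pairwise
  variant constraints are imposed by iterative proportional fitting to
  1e-10, and unspecified interactions take the maximum-entropy
  completion. An infeasible constraint set raises an error naming the
  worst pair.
* `enumerateDiplotypes()` forms diplotypes by random union of
  haplotypes (Hardy–Weinberg) conditioned on marker heterozygosity.
  Each variant gets a phase state s ∈ {+1, 0, −1}: high-expression
  allele on the M haplotype, homozygous, or on the m haplotype.
* The expected log2AEI of a configuration is Σ effect·s — effects
  combine **additively on the log2 scale** (multiplicatively on
  expression). The source assay never states the combination rule; we
  declare additivity as the natural reading rather than inferring it
  from data.
* Trans-acting variants scale both alleles equally and cancel in the
  ratio; they and other unmodeled factors appear only inside `noiseSd`.

`predictMixture()` returns the exact discrete mixture (support,
weights) convolved with Gaussian noise; `predictDistribution()` draws a
sorted sample. Two closed-form limits anchor the model: complete
coupling with matched frequencies (D′ = 1, P = P(M)) puts every
heterozygote at exactly |effect|, and an unlinked variant at P = 0.5
gives phase probabilities (¼, ¼, ½).

`fitModel()` recovers parameters by deterministic grid search,
minimizing the mean squared difference between observed order
statistics and the mixture quantiles at plotting positions
(i − 0.5)/n. The marker frequency is not searched — it is measured
directly from the cohort's genotypes. Grid search was chosen over
gradient methods because the objective is piecewise-smooth in D′ and
the parameter count is small; the k = 1 path caches the Gaussian CDF
components per effect value, making 50 fits of n = 30 distributions run
in well under a minute. Objective ties are broken toward parsimony:
fewest active variants, then smallest total |effect| (total effect
alone cannot separate, e.g., two coupled variants of 0.4 from one of
0.8). A depth-dependent error curve can stand in for the constant
noise SD via sd = E/1.96, collapsed to the root mean square across
records.

## What the synthetic data emulate

`studyDesign()`/`generateStudy()` reproduce the study conditions this
assay was characterized under: 52 samples; 70 genes (42 with a strong
fully marker-linked variant, effects 0.6–1.2; 20 with a modest variant
at a low-frequency marker, so few heterozygotes; 8 null); per-gene
amplification bias drawn from [0.67, 1.5]; read depths log-uniform over
1,079–33,250 (gDNA) and 1,277–75,440 (cDNA); heterozygote counts
emerging from Hardy–Weinberg at each gene's marker frequency (the
observed per-gene range is about 3–36). Counts are binomial: the
M-allele probability is b/(1+b) for gDNA and br/(1+br) for cDNA, with b
the bias and r the true expression ratio. Fully linked variants use
P = P(M) so that all heterozygotes share one phase — this makes planted
per-gene categories robust to sampling noise. `generateFastq()` plants
read-level triage categories (30% unmatchable, 3% truncated before the
mSNP, 85% of usable reads full-length at 76 bp) with deterministic
counts, and records every read's origin in a truth table.

What the generator does **not** emulate: base-quality error profiles,
PCR duplicates and flow-cell artifacts; overdispersion beyond binomial
sampling in counts; genotyping error (except as the single-allele-only
flag exercised directly); pseudogene co-amplification. Passing tests on
synthetic data therefore demonstrate correctness of the computations
and calibration under the declared noise model, not robustness to every
artifact of real libraries.

Problem sizes in the test-suite simulations (20 genes × 10 samples ×
10,000 reads for correction recovery, 50 replicates of n = 30 for
parameter recovery, ~5,000–10,000 reads per FASTQ fixture, 10^5 draws
for mixture checks) were chosen so that Monte-Carlo error is a small
fraction of each assertion's tolerance.

## Known limitations

* Only single-end reads with a leading fixed-length index; no gapped
  alignment, adapter trimming or quality filtering.
* Significance is called per sample against an error envelope, not via
  p-values; no multiple-testing machinery across genes.
* The distribution model fits at most four variants, assumes additive
  log2 effects, Hardy–Weinberg mating, and represents all trans and
  non-genetic structure as one Gaussian term; D′ and P are partially
  confounded at small sample sizes, so D′ is the harder parameter to
  pin down (median |error| ≈ 0.1 at n = 30 in our recovery
  simulations, versus ≈ 0 for the effect size).
* Replicate-concordance r² is uninformative for genes whose log2AEI
  distribution spans a narrow range, however well the assays agree.
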