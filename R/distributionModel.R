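## Population-genetic model of log2 AEI distributions.
##
## Each gene's ordered log2 AEI distribution across heterozygous
## samples is modeled from cis-regulatory variants: their
## high-expression-allele frequencies, additive log2 effects, and
## linkage disequilibrium (D') to the marker SNP. Conditioning on
## marker heterozygosity, each diplotype assigns every variant a phase
## state s in {+1, 0, -1} (high allele on the M haplotype / homozygous /
## high allele on the m haplotype) and contributes effect * s to the
## expected log2 AEI. Trans-acting and unmodeled factors enter as
## Gaussian noise on the log2 scale.

#' Construct a RegulatoryModel
#'
#' @param markerFreq frequency of the marker SNP's M allele, in (0,1).
#' @param variants data.frame with columns `name`, `P`
#'   (high-expression-allele frequency), `effect` (signed log2
#'   contribution when the high allele phases with M), `dprime_marker`
#'   (D' to the marker, in [-1,1]). May be empty (pure-noise model).
#' @param noiseSd Gaussian noise SD in log2 units (default 0).
#' @param pairwiseDprime optional symmetric named matrix of D' between
#'   variants; NA entries are left unconstrained (maximum-entropy
#'   completion).
#' @return a [RegulatoryModel-class].
#' @examples
#' # single fully linked variant: the uniphasic archetype
#' regulatoryModel(0.5, variantTable("A", P = 0.5, effect = 0.8,
#'                                   dprime_marker = 1), noiseSd = 0.1)
#' @export
regulatoryModel <- function(markerFreq, variants = variantTable(),
                            noiseSd = 0, pairwiseDprime = NULL) {
  new("RegulatoryModel", markerFreq = markerFreq,
      variants = variants, pairwiseDprime = pairwiseDprime,
      noiseSd = noiseSd)
}

#' @rdname regulatoryModel
#' @param name,P,effect,dprime_marker vectors defining one row per
#'   variant.
#' @export
variantTable <- function(name = character(), P = numeric(),
                         effect = numeric(), dprime_marker = numeric()) {
  data.frame(name = as.character(name), P = P, effect = effect,
             dprime_marker = dprime_marker, stringsAsFactors = FALSE)
}

#' Two-locus haplotype frequencies from allele frequencies and D'
#'
#' Standard decomposition: `D = dprime * Dmax`, with
#' `Dmax = min(pA(1-pM), (1-pA)pM)` for positive D' and
#' `min(pA pM, (1-pA)(1-pM))` for negative D'; then
#' `f(AM) = pA pM + D` and so on. All four frequencies are non-negative
#' and reproduce the marginals for any |D'| <= 1.
#'
#' @param pA,pM allele frequencies in (0,1) (A and M are the
#'   high-expression and marker alleles respectively).
#' @param dprime normalized linkage disequilibrium in [-1,1].
#' @return named numeric vector `c(AM, Am, aM, am)`.
#' @examples
#' haplotypeFreqs(0.5, 0.5, 1)   # complete coupling: (0.5, 0, 0, 0.5)
#' @export
haplotypeFreqs <- function(pA, pM, dprime) {
  if (pA <= 0 || pA >= 1 || pM <= 0 || pM >= 1)
    stop("allele frequencies must lie strictly in (0, 1)")
  if (abs(dprime) > 1) stop("dprime must lie in [-1, 1]")
  Dmax <- if (dprime >= 0) min(pA * (1 - pM), (1 - pA) * pM)
          else min(pA * pM, (1 - pA) * (1 - pM))
  D <- dprime * Dmax
  f <- c(AM = pA * pM + D, Am = pA * (1 - pM) - D,
         aM = (1 - pA) * pM - D, am = (1 - pA) * (1 - pM) + D)
  f[abs(f) < 1e-15] <- 0
  f
}

#' Joint haplotype distribution over all variants and the marker
#'
#' Exact enumeration over the `2^(k+1)` haplotypes of k (<= 4) variants
#' plus the marker SNP. The joint reproduces every allele frequency and
#' every variant-marker D'; where pairwise D' between variants is
#' specified it additionally matches those two-locus tables. The
#' completion is maximum-entropy, obtained by iterative proportional
#' fitting (IPF) of the constraint tables to tolerance 1e-10;
#' an infeasible constraint set raises an error naming the worst pair.
#'
#' @param model a [RegulatoryModel-class].
#' @param tol IPF convergence tolerance (default 1e-10).
#' @param maxIter maximum IPF sweeps (default 10000).
#' @return data.frame with one row per haplotype: a 0/1 column per
#'   variant (1 = high-expression allele), a 0/1 `M` column
#'   (1 = marker M allele) and `freq`.
#' @export
buildJoint <- function(model, tol = 1e-10, maxIter = 10000L) {
  v <- modelVariants(model)
  k <- nrow(v)
  if (k > 4) stop("at most 4 variants are supported (exact enumeration)")
  pM <- markerFreq(model)
  loci <- c(v$name, ".M")
  freqs <- c(v$P, pM)
  grid <- do.call(expand.grid, rep(list(c(1L, 0L)), k + 1L))
  names(grid) <- loci
  ## start from independence
  f <- rep(1, nrow(grid))
  for (j in seq_len(k + 1L))
    f <- f * ifelse(grid[[j]] == 1L, freqs[j], 1 - freqs[j])

  ## constraint tables: every variant against the marker, plus any
  ## specified variant pairs
  constraints <- list()
  for (i in seq_len(k)) {
    constraints[[length(constraints) + 1L]] <- list(
      a = v$name[i], b = ".M",
      table = haplotypeFreqs(v$P[i], pM, v$dprime_marker[i]))
  }
  pw <- model@pairwiseDprime
  if (!is.null(pw) && k >= 2) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      ni <- v$name[i]; nj <- v$name[j]
      d <- NA_real_
      if (ni %in% rownames(pw) && nj %in% colnames(pw)) d <- pw[ni, nj]
      if (is.na(d) && nj %in% rownames(pw) && ni %in% colnames(pw))
        d <- pw[nj, ni]
      if (!is.na(d))
        constraints[[length(constraints) + 1L]] <- list(
          a = ni, b = nj, table = haplotypeFreqs(v$P[i], v$P[j], d))
    }
  }
  cellIndex <- function(a, b)
    factor(paste(grid[[a]], grid[[b]]), levels = c("1 1", "1 0", "0 1", "0 0"))
  residual <- function() {
    worst <- 0; worst_pair <- ""
    for (con in constraints) {
      marg <- tapply(f, cellIndex(con$a, con$b), sum, default = 0)
      r <- max(abs(marg - con$table))
      if (r > worst) { worst <- r; worst_pair <- paste(con$a, con$b) }
    }
    list(worst = worst, pair = worst_pair)
  }
  if (length(constraints)) {
    for (iter in seq_len(maxIter)) {
      for (con in constraints) {
        ci <- cellIndex(con$a, con$b)
        marg <- tapply(f, ci, sum, default = 0)
        scale <- ifelse(marg > 0, con$table / marg, 0)
        f <- f * scale[as.integer(ci)]
      }
      r <- residual()
      if (r$worst < tol) break
    }
    r <- residual()
    if (r$worst >= tol)
      stop("IPF did not converge; constraint set infeasible near pair ",
           r$pair, " (residual ", signif(r$worst, 3), ")")
  }
  grid$freq <- f / sum(f)
  names(grid)[k + 1L] <- "M"
  grid
}

#' Enumerate diplotypes conditional on marker heterozygosity
#'
#' Diplotypes are formed by random union of haplotypes (Hardy-Weinberg)
#' and renormalized over the event of one M and one m haplotype. Each
#' configuration records, per variant, the phase state s: +1 when the
#' high-expression allele sits on the M haplotype and the low allele on
#' the m haplotype, -1 for the reverse phase, 0 when the variant is
#' homozygous.
#'
#' @param joint data.frame from [buildJoint()].
#' @return data.frame with one `s_<name>` column per variant and `prob`
#'   (summing to 1).
#' @export
enumerateDiplotypes <- function(joint) {
  vnames <- setdiff(names(joint), c("M", "freq"))
  pM <- sum(joint$freq[joint$M == 1L])
  if (pM <= 0 || pM >= 1)
    stop("no marker heterozygotes exist when P(M) is 0 or 1")
  hM <- joint[joint$M == 1L, , drop = FALSE]
  hm <- joint[joint$M == 0L, , drop = FALSE]
  pairs <- expand.grid(i = seq_len(nrow(hM)), j = seq_len(nrow(hm)))
  prob <- hM$freq[pairs$i] * hm$freq[pairs$j] / (pM * (1 - pM))
  s <- matrix(0, nrow(pairs), length(vnames),
              dimnames = list(NULL, if (length(vnames))
                paste0("s_", vnames) else NULL))
  for (v in seq_along(vnames))
    s[, v] <- hM[[vnames[v]]][pairs$i] - hm[[vnames[v]]][pairs$j]
  key <- apply(s, 1L, paste, collapse = ",")
  agg <- rowsum(prob, key)
  uniq <- s[!duplicated(key), , drop = FALSE]
  out <- as.data.frame(uniq[match(rownames(agg), unique(key)), ,
                            drop = FALSE])
  out$prob <- as.numeric(agg)
  out <- out[out$prob > 1e-15, , drop = FALSE]
  out$prob <- out$prob / sum(out$prob)
  rownames(out) <- NULL
  out
}

#' Expected log2 AEI of a diplotype configuration
#'
#' Effects combine additively on the log2 scale (multiplicatively on
#' expression): the expected log2 AEI is the sum over variants of
#' `effect * s`.
#'
#' @param configs data.frame from [enumerateDiplotypes()].
#' @param effects numeric vector of per-variant effects, in the order of
#'   the model's variants.
#' @return numeric vector of expected log2 AEI, one per configuration.
#' @export
expectedLog2AEI <- function(configs, effects) {
  scols <- grep("^s_", names(configs), value = TRUE)
  if (length(scols) != length(effects))
    stop("effects must match the number of variants")
  if (!length(scols)) return(rep(0, nrow(configs)))
  as.numeric(as.matrix(configs[scols]) %*% effects)
}

#' Exact mixture of expected log2 AEI values
#'
#' Collapses the diplotype enumeration to the distinct expected log2
#' AEI values with their probabilities; with `noiseSd > 0` the
#' population distribution is this discrete mixture convolved with
#' Gaussian noise.
#'
#' @param model a [RegulatoryModel-class].
#' @return list with `support`, `weights`, `noise_sd`.
#' @export
predictMixture <- function(model) {
  joint <- buildJoint(model)
  cfg <- enumerateDiplotypes(joint)
  mu <- expectedLog2AEI(cfg, modelVariants(model)$effect)
  agg <- rowsum(cfg$prob, round(mu, 12))
  list(support = as.numeric(rownames(agg)), weights = as.numeric(agg),
       noise_sd = noiseSd(model))
}

#' Mixture CDF and quantiles
#'
#' CDF and quantile function of a Gaussian-convolved discrete mixture
#' as returned by [predictMixture()]. With `noise_sd = 0` the discrete
#' step CDF and its type-1 inverse are used.
#'
#' @param mixture list with `support`, `weights`, `noise_sd`.
#' @param x,probs evaluation points.
#' @return numeric vector.
#' @export
mixtureCDF <- function(mixture, x) {
  s <- mixture$noise_sd
  if (s > 0) {
    out <- numeric(length(x))
    for (j in seq_along(mixture$support))
      out <- out + mixture$weights[j] *
        stats::pnorm((x - mixture$support[j]) / s)
    out
  } else {
    vapply(x, function(xi)
      sum(mixture$weights[mixture$support <= xi]), numeric(1))
  }
}

#' @rdname mixtureCDF
#' @export
mixtureQuantile <- function(mixture, probs) {
  s <- mixture$noise_sd
  if (s == 0) {
    o <- order(mixture$support)
    cw <- cumsum(mixture$weights[o])
    idx <- vapply(probs, function(p) which(cw >= p - 1e-12)[1], integer(1))
    return(mixture$support[o][idx])
  }
  lo <- min(mixture$support) - 8 * s
  hi <- max(mixture$support) + 8 * s
  grid <- seq(lo, hi, length.out = 1024L)
  cdf <- mixtureCDF(mixture, grid)
  stats::approx(cdf, grid, xout = probs, rule = 2, ties = "ordered")$y
}

#' Predict an ordered log2 AEI distribution
#'
#' Draws `nSamples` heterozygous individuals from the model (diplotype
#' configuration plus Gaussian noise) and returns the values sorted
#' ascending, the form in which assay distributions are displayed.
#'
#' @param model a [RegulatoryModel-class].
#' @param nSamples number of heterozygous samples (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return sorted numeric vector of log2 AEI values.
#' @export
predictDistribution <- function(model, nSamples, seed = NULL) {
  if (nSamples < 1) stop("nSamples must be at least 1")
  mix <- predictMixture(model)
  withSeed(seed, {
    idx <- sample.int(length(mix$support), nSamples, replace = TRUE,
                      prob = mix$weights)
    vals <- mix$support[idx]
    if (mix$noise_sd > 0)
      vals <- vals + stats::rnorm(nSamples, 0, mix$noise_sd)
    sort(vals)
  })
}

#' Classify the shape of a log2 AEI distribution
#'
#' Patterns of ordered log2 AEI distributions: `null` when no value is
#' significant at the threshold; `uniphasic` when all significant values
#' share one sign (complete linkage of a single regulator to the marker
#' SNP); `biphasic` when the minority sign makes up at least
#' `biphasicFrac` of the significant values (regulators unlinked to the
#' marker); `skewed` otherwise (partial linkage).
#'
#' @param values numeric vector of log2 AEI ratios (>= 5 values).
#' @param threshold significance threshold in log2 units (default 0.29).
#' @param biphasicFrac minority-sign fraction defining biphasic
#'   (default 0.25).
#' @return one of `"null"`, `"uniphasic"`, `"skewed"`, `"biphasic"`.
#' @export
classifyShape <- function(values, threshold = 0.29, biphasicFrac = 0.25) {
  if (length(values) < 5L) stop("at least 5 values are required")
  sig <- values[abs(values) > threshold]
  if (!length(sig)) return("null")
  npos <- sum(sig > 0); nneg <- sum(sig < 0)
  minority <- min(npos, nneg)
  if (minority == 0L) return("uniphasic")
  if (minority / length(sig) >= biphasicFrac) return("biphasic")
  "skewed"
}

## fast closed-form phase probabilities for a single-variant model
phaseProbsK1 <- function(P, pM, dprime) {
  f <- haplotypeFreqs(P, pM, dprime)
  het <- pM * (1 - pM)
  pr <- c(plus = unname(f["AM"] * f["am"] / het),
          minus = unname(f["Am"] * f["aM"] / het))
  pr <- c(pr, zero = max(0, 1 - sum(pr)))
  pr / sum(pr)
}

#' Fit a regulatory model to an observed log2 AEI distribution
#'
#' Deterministic grid search over per-variant frequency, effect and D'
#' to the marker, minimizing the mean squared difference between the
#' observed order statistics and the model mixture's quantiles at
#' plotting positions `(i - 0.5) / n`. Ties (objectives within
#' `tieTol` of the minimum) are broken toward the weakest architecture,
#' i.e. smallest total |effect|.
#'
#' @param observed numeric vector of observed log2 AEI ratios (>= 5).
#' @param markerFreq frequency of the marker M allele (taken as known:
#'   it is measured directly from the cohort's genotypes).
#' @param k number of variants, 1-3 (default 1).
#' @param noiseSd measurement/residual noise SD in log2 units; a vector
#'   (e.g. per-point bounds `E/1.96` from an [ErrorCurve-class]) is
#'   collapsed to its root mean square.
#' @param grid list with numeric vectors `P`, `effect`, `dprime`
#'   defining the per-variant search grid.
#' @param tieTol absolute objective tolerance for parsimony tie-breaks.
#' @return list with `model` (the best-fit [RegulatoryModel-class]),
#'   `objective`, and `fitted` (mixture quantiles at the plotting
#'   positions).
#' @export
fitModel <- function(observed, markerFreq, k = 1L, noiseSd = 0.1,
                     grid = list(P = seq(0.1, 0.9, by = 0.1),
                                 effect = seq(0, 1.6, by = 0.05),
                                 dprime = seq(-1, 1, by = 0.05)),
                     tieTol = 1e-8) {
  if (length(observed) < 5L) stop("at least 5 observed values are required")
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  sd0 <- sqrt(base::mean(noiseSd^2))
  if (sd0 <= 0) sd0 <- 1e-6
  obs <- sort(observed)
  n <- length(obs)
  pp <- (seq_len(n) - 0.5) / n
  if (stats::sd(observed) == 0)
    warning("observed values are all identical; objective is flat in D'")

  if (k == 1L) {
    combos <- expand.grid(P = grid$P, effect = grid$effect,
                          dprime = grid$dprime)
    ## shared x-grid; per-|effect| Gaussian CDF components reused
    emax <- max(abs(grid$effect))
    xg <- seq(min(obs, -emax) - 6 * sd0, max(obs, emax) + 6 * sd0,
              length.out = 1024L)
    F0 <- stats::pnorm(xg / sd0)
    Fcache <- lapply(grid$effect, function(e)
      cbind(stats::pnorm((xg - e) / sd0), stats::pnorm((xg + e) / sd0)))
    names(Fcache) <- as.character(grid$effect)
    objs <- numeric(nrow(combos))
    for (r in seq_len(nrow(combos))) {
      pr <- phaseProbsK1(combos$P[r], markerFreq, combos$dprime[r])
      FF <- Fcache[[as.character(combos$effect[r])]]
      cdf <- pr[1] * FF[, 1] + pr[2] * FF[, 2] + pr[3] * F0
      q <- stats::approx(cdf, xg, xout = pp, rule = 2, ties = "ordered")$y
      objs[r] <- base::mean((obs - q)^2)
    }
    best <- which(objs <= min(objs) + tieTol)
    sel <- best[order(abs(combos$effect[best]),
                      abs(combos$dprime[best]))][1L]
    model <- regulatoryModel(markerFreq,
                             variantTable("A", combos$P[sel],
                                          combos$effect[sel],
                                          combos$dprime[sel]),
                             noiseSd = sd0)
    fitted <- mixtureQuantile(predictMixture(model), pp)
    return(list(model = model, objective = objs[sel], fitted = fitted))
  }

  ## k >= 2: generic (slower) enumeration over per-variant combos
  per <- expand.grid(P = grid$P, effect = grid$effect, dprime = grid$dprime)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(per))), k))
  ## unordered variant sets: keep non-decreasing index tuples only
  keep <- rep(TRUE, nrow(idx))
  for (j in seq_len(k - 1L)) keep <- keep & idx[[j]] <= idx[[j + 1L]]
  idx <- idx[keep, , drop = FALSE]
  bestObj <- Inf; bestSel <- NULL; bestKey <- c(Inf, Inf)
  for (r in seq_len(nrow(idx))) {
    rows <- per[as.integer(idx[r, ]), , drop = FALSE]
    m <- regulatoryModel(markerFreq,
                         variantTable(LETTERS[seq_len(k)], rows$P,
                                      rows$effect, rows$dprime),
                         noiseSd = sd0)
    q <- mixtureQuantile(predictMixture(m), pp)
    obj <- base::mean((obs - q)^2)
    ## parsimony: fewer active variants first, then smaller total effect
    key <- c(sum(abs(rows$effect) > 0), sum(abs(rows$effect)))
    better <- obj < bestObj - tieTol ||
      (obj <= bestObj + tieTol &&
         (key[1] < bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2])))
    if (better) { bestObj <- obj; bestSel <- m; bestKey <- key }
  }
  fitted <- mixtureQuantile(predictMixture(bestSel), pp)
  list(model = bestSel, objective = bestObj, fitted = fitted)
}

#' Read or write a regulatory model spec (YAML/JSON)
#'
#' The on-disk form is `{marker_freq, noise_sd, variants: [{name, P,
#' effect, dprime_marker}, ...]}`.
#'
#' @param model a [RegulatoryModel-class].
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `readModelSpec`: a [RegulatoryModel-class];
#'   `writeModelSpec`: the path, invisibly.
#' @export
readModelSpec <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  v <- obj$variants
  vt <- if (is.null(v) || (is.data.frame(v) && !nrow(v)) || !length(v))
    variantTable()
  else if (is.data.frame(v))
    variantTable(v$name, v$P, v$effect, v$dprime_marker)
  else do.call(rbind, lapply(v, function(x)
    variantTable(x$name, x$P, x$effect, x$dprime_marker)))
  regulatoryModel(obj$marker_freq, vt, noiseSd = obj$noise_sd %||% 0)
}

#' @rdname readModelSpec
#' @export
writeModelSpec <- function(model, path) {
  v <- modelVariants(model)
  obj <- list(marker_freq = markerFreq(model), noise_sd = noiseSd(model),
              variants = lapply(seq_len(nrow(v)), function(i)
                list(name = v$name[i], P = v$P[i], effect = v$effect[i],
                     dprime_marker = v$dprime_marker[i])))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}
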