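## Measurement-error models for log2 AEI ratios.
##
## Genomic DNA from heterozygotes carries the two alleles 1:1, so the
## spread of normalized gDNA ratios around 1 is a direct readout of
## experimental error. Two estimators are provided: whole-distribution
## statistics of the normalized gDNA ratios, and an empirical
## "rectangle" bound E(X) as a function of read depth, alongside the
## theoretical binomial sampling envelope.

#' Distribution statistics of normalized gDNA ratios
#'
#' Mean, SD and SEM of the normalized gDNA linear ratios and the central
#' 95% interval (empirical 2.5/97.5 percentiles) on both the linear and
#' log2 scales.
#'
#' @param ratios numeric vector of normalized gDNA linear ratios.
#' @param probs lower/upper percentile pair (default `c(0.025, 0.975)`).
#' @return list with `n`, `mean`, `sd`, `sem`, `interval_linear`,
#'   `interval_log2`.
#' @export
gdnaDistributionStats <- function(ratios, probs = c(0.025, 0.975)) {
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n < 2L) stop("at least 2 gDNA ratios are required")
  if (n < 20L)
    warning("fewer than 20 gDNA ratios; interval estimates are unstable")
  q <- unname(stats::quantile(ratios, probs))
  list(n = n, mean = base::mean(ratios), sd = stats::sd(ratios),
       sem = stats::sd(ratios) / sqrt(n),
       interval_linear = q, interval_log2 = log2(q))
}

#' Theoretical binomial sampling envelope for log2 AEI
#'
#' With both alleles at frequency 0.5 in a heterozygote's gDNA, the
#' M-allele read count is X ~ Binomial(N, 0.5); the envelope is the
#' log2 ratio at the exact binomial quantiles \eqn{(1 \pm c)/2}. Counts
#' of 0 or N (where the ratio is undefined) are truncated to the
#' nearest interior count.
#'
#' @param N read depth (>= 10), may be a vector.
#' @param p allele frequency (default 0.5).
#' @param confidence confidence level (default 0.95).
#' @return for scalar `N`, a named vector `c(lower, upper)` of log2
#'   bounds; for vector `N`, a two-column matrix.
#' @examples
#' binomialEnvelope(1000)   # ~ -0.179, +0.179
#' @export
binomialEnvelope <- function(N, p = 0.5, confidence = 0.95) {
  if (any(N < 10)) stop("N must be at least 10")
  alpha <- (1 - confidence) / 2
  qlo <- stats::qbinom(alpha, N, p)
  qhi <- stats::qbinom(1 - alpha, N, p)
  qlo <- pmax(qlo, 1L)
  qhi <- pmin(qhi, N - 1L)
  out <- cbind(lower = log2(qlo / (N - qlo)), upper = log2(qhi / (N - qhi)))
  if (length(N) == 1L) out[1L, ] else out
}

#' Rectangle estimate of experimental error at a read-depth threshold
#'
#' Among gDNA measurements with more than `X` reads, the bound E such
#' that a `confidence` fraction of |log2 ratio| values fall within
#' [-E, E]: equivalently, the smallest symmetric rectangle about the
#' read-count axis containing that fraction of the points. Implemented
#' as the order statistic of |log2 ratio| at rank
#' `ceiling(confidence * n)`.
#'
#' @param points data.frame with columns `log2_ratio` and `reads`.
#' @param X read-count threshold (points with `reads > X` are used).
#' @param confidence confidence level (default 0.95).
#' @param minPoints minimum number of points beyond X (default 20).
#' @return the error bound E (log2 units), or `NA` if fewer than
#'   `minPoints` points lie beyond X.
#' @export
rectangleErrorEstimate <- function(points, X, confidence = 0.95,
                                   minPoints = 20L) {
  stopifnot_cols(points, c("log2_ratio", "reads"), "error points")
  v <- abs(points$log2_ratio[points$reads > X])
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < minPoints) return(NA_real_)
  sort(v)[ceiling(confidence * n)]
}

#' Build an empirical error curve over a read-depth grid
#'
#' Applies [rectangleErrorEstimate()] at each grid threshold and
#' enforces the monotone non-increasing shape by isotonic regression
#' (sampling noise can otherwise invert adjacent points). The default
#' grid spans the depths at which the assay operates, including the
#' anchors 1,000 / 13,500 / 24,300 reads.
#'
#' @param points data.frame with columns `log2_ratio` and `reads`.
#' @param Xgrid increasing vector of read-count thresholds.
#' @param confidence confidence level.
#' @param minPoints minimum points per threshold; thresholds with fewer
#'   are omitted from the curve.
#' @return an [ErrorCurve-class].
#' @export
buildErrorCurve <- function(points,
                            Xgrid = c(500, 1000, 2000, 5000, 10000,
                                      13500, 24300, 50000),
                            confidence = 0.95, minPoints = 20L) {
  if (!length(Xgrid)) stop("Xgrid must contain at least one threshold")
  if (is.unsorted(Xgrid, strictly = TRUE))
    stop("Xgrid must be strictly increasing")
  E <- vapply(Xgrid, function(x)
    rectangleErrorEstimate(points, x, confidence, minPoints), numeric(1))
  keep <- !is.na(E)
  if (!any(keep))
    stop("no grid threshold retains at least ", minPoints, " points")
  X <- Xgrid[keep]; E <- E[keep]
  if (length(E) > 1L) {
    ## isotonic fit of -E against X gives the closest non-increasing curve
    E <- -stats::isoreg(X, -E)$yf
  }
  new("ErrorCurve", confidence = confidence,
      points = data.frame(X = X, E = E))
}

#' @rdname errorAt
#' @export
setMethod("errorAt", "ErrorCurve", function(x, reads) {
  pts <- x@points
  idx <- findInterval(reads, pts$X)
  below <- idx == 0L
  if (any(below)) {
    warning(sum(below), " read depth(s) below the smallest threshold; ",
            "using the largest error bound")
    idx[below] <- 1L
  }
  pts$E[idx]
})

#' Serialize / deserialize an error curve as JSON
#'
#' @param curve an [ErrorCurve-class].
#' @param path file path.
#' @return `writeErrorCurve`: the path, invisibly; `readErrorCurve`: an
#'   [ErrorCurve-class].
#' @export
writeErrorCurve <- function(curve, path) {
  obj <- list(confidence = curve@confidence,
              points = unname(apply(curve@points, 1L, as.numeric,
                                    simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeErrorCurve
#' @export
readErrorCurve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  new("ErrorCurve", confidence = obj$confidence,
      points = data.frame(X = pts[, 1], E = pts[, 2]))
}
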