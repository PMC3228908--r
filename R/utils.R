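#' Convert between log2 and linear AEI ratios
#'
#' AEI ratios are reported both on the linear scale (numerator-allele
#' count over denominator-allele count) and on the log2 scale, where
#' equal displacement of over- and under-expression is symmetric about 0.
#'
#' @param x numeric vector of log2 ratios (for `log2ToLinear`) or linear
#'   ratios (for `linearToLog2`; must be strictly positive).
#' @return numeric vector on the other scale.
#' @examples
#' log2ToLinear(0.29)   # ~1.22, the linear significance bound
#' linearToLog2(0.82)   # ~-0.29
#' @export
log2ToLinear <- function(x) 2^x

#' @rdname log2ToLinear
#' @export
linearToLog2 <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    stop("linear AEI ratios must be strictly positive")
  log2(x)
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. Mersenne-Twister + Inversion are pinned so synthetic data are
## reproducible across platforms.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  expr
}

## Derive a stream of child seeds from one master seed (keeps values
## well inside 32-bit integer range).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max %/% 4L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
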