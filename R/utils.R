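# Internal helpers shared across modules. Coordinates are 0-based half-open
# throughout the package (BED convention); IRanges calls convert locally.

#' @import methods
#' @importFrom stats rpois rnorm runif rmultinom lm coef median quantile sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# 0-based half-open [start, end) -> IRanges (1-based inclusive)
.ir <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Sum of per-base values of an Rle over 0-based half-open windows, clamped to
# the sequence; bases outside the sequence contribute 0.
.window_sums <- function(rle, start, end) {
  n <- length(rle)
  s <- pmax(start + 1, 1)
  e <- pmin(end, n)
  out <- numeric(length(start))
  ok <- which(e >= s & end > start)
  if (length(ok)) {
    v <- IRanges::Views(rle, start = s[ok], end = e[ok])
    out[ok] <- IRanges::viewSums(v)
  }
  out
}

# Mean per-base value over 0-based half-open windows; width taken as the
# *requested* width so out-of-bounds bases count as zero coverage.
.window_means <- function(rle, start, end) {
  .window_sums(rle, start, end) / pmax(end - start, 1)
}

# Centered running mean with partial windows at the edges.
.runmean <- function(x, k) {
  if (k <= 1L) return(x)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
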