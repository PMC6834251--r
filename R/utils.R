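## small numeric utilities shared across modules

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric upper-tail probability by direct log-space summation
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: the number of "marked"
#' elements in a size-`n` draw without replacement from a universe of `M`
#' elements of which `K` are marked.  Summation is performed on log binomial
#' coefficients to stay accurate for tail probabilities far below double
#' underflow of individual terms.
#'
#' @param k observed count (integer >= 0).
#' @param M universe size.
#' @param K number of marked elements in the universe.
#' @param n draw size.
#' @return upper-tail probability in `(0, 1]` (exactly 1 when `k` is at or
#'   below the distribution's minimum support).
#' @examples
#' hyperUpperTail(3, 10, 3, 3)   # 1/choose(10,3)
#' @export
hyperUpperTail <- function(k, M, K, n) {
  stopifnot(M >= 0, K >= 0, K <= M, n >= 0, n <= M)
  lo <- max(0L, K + n - M)
  hi <- min(K, n)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  j <- seq.int(k, hi)
  lt <- lchoose(K, j) + lchoose(M - K, n - j) - lchoose(M, n)
  min(exp(logSumExp(lt)), 1)
}

## counter-based fan-out of one user-facing seed into per-stage seeds;
## kept below 2^31 so set.seed() always accepts the value
stageSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + 104729 * counter) %% 2147483647)
}

## format doubles so that write -> read round-trips bit-identically
fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
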