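#' Upper-tail hypergeometric probability
#'
#' The probability of observing at least `k` marked items when drawing `n`
#' items without replacement from a universe of `N` items of which `K` are
#' marked: `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`
#' (inclusive upper tail). This single kernel backs both the shared-miRNA
#' ceRNA test and the over-representation analysis, so the two agree
#' bit-for-bit on identical `(N, K, n, k)`.
#'
#' @param k Observed overlap (vectorized).
#' @param K Number of marked items in the universe.
#' @param n Number of items drawn.
#' @param N Universe size.
#' @return Probabilities in `[0, 1]`; `k <= 0` gives exactly 1.
#' @examples
#' hyper_upper_p(3, K = 3, n = 4, N = 10) # 7/210
#' @export
hyper_upper_p <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop_("K and n must not exceed the universe size N")
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0)) {
    stop_("hypergeometric arguments must be non-negative")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
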