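#' Cumulative hypergeometric upper-tail probability
#'
#' The co-mention association statistic: the probability of observing at
#' least `n` marked items when drawing `k` items without replacement from a
#' pool of `N` items of which `M` are marked,
#' \deqn{P = 1 - \sum_{i=0}^{n-1} \binom{M}{i}\binom{N-M}{k-i} / \binom{N}{k}
#'         = P(X \ge n), \quad X \sim \mathrm{Hypergeom}(N, M, k).}
#' The default `k = n` is the literal form used for literature co-mention
#' counts (draw size equal to the observed overlap); passing `k` explicitly
#' gives the standard 2x2 co-occurrence parameterization (`N` = all
#' documents, `M` = documents about a, `k` = documents about b, `n` =
#' documents about both). Terms are accumulated on the log scale
#' (log-gamma binomial coefficients), so corpus-scale counts do not
#' overflow; the upper tail is summed directly for accuracy at small p.
#'
#' @param N Pool size (total documents in the chosen parameterization).
#' @param M Number of marked items (documents about disease a).
#' @param n Observed overlap (documents about both diseases).
#' @param k Draw size; defaults to `n`.
#' @return Vector of upper-tail probabilities in `[0, 1]`. `n = 0` gives
#'   exactly 1 (empty sum).
#' @export
#' @examples
#' hypergeom_upper_tail(N = 10, M = 5, n = 3) # = choose(5,3)/choose(10,3)
#' hypergeom_upper_tail(N = 1000, M = 100, n = 30, k = 150)
hypergeom_upper_tail <- function(N, M, n, k = n) {
  len <- max(length(N), length(M), length(n), length(k))
  N <- rep_len(as.numeric(N), len); M <- rep_len(as.numeric(M), len)
  n <- rep_len(as.numeric(n), len); k <- rep_len(as.numeric(k), len)
  if (any(is.na(N) | is.na(M) | is.na(n) | is.na(k))) {
    stop_validation("Counts must not be missing.")
  }
  if (any(N < 0 | M < 0 | n < 0 | k < 0) ||
      any(c(N, M, n, k) != floor(c(N, M, n, k)))) {
    stop_validation("Counts must be non-negative integers.")
  }
  if (any(M > N)) stop_validation("Require M <= N.")
  if (any(k > N)) stop_validation("Require draw size k <= N.")
  if (any(n > k) || any(n > M)) stop_validation("Require n <= min(M, k).")

  vapply(seq_len(len), function(j) {
    if (n[j] == 0) return(1)
    i <- seq(n[j], min(k[j], M[j]))
    i <- i[k[j] - i <= N[j] - M[j]]
    if (!length(i)) return(0)
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], k[j] - i) - lchoose(N[j], k[j])
    m <- max(lt)
    min(1, max(0, exp(m + log(sum(exp(lt - m))))))
  }, numeric(1))
}
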