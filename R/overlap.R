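# Treatment-overlap statistics: upper-tail hypergeometric test and the
# representation factor RF = k*N/(K*n), the observed overlap divided by the
# overlap expected if the two sets were drawn independently.

# log(sum(exp(lx))) without leaving log space.
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Hypergeometric overlap test with representation factor
#'
#' For two feature sets of sizes `K` and `n` drawn from a universe of `N`
#' features with observed overlap `k`, computes the upper-tail (enrichment)
#' probability P(X >= k) for X ~ Hypergeometric(N, K, n), the point
#' probability P(X = k), and the representation factor. The tail is
#' accumulated in log space from log-binomial coefficients, so p-values far
#' below 1e-300 are still meaningful through `log_p`.
#'
#' The point probability `p_point` is reported alongside the tail because
#' some published overlap analyses print it in place of the cumulative
#' tail; having both makes results comparable with either convention.
#'
#' @param k overlap count.
#' @param K size of set 1.
#' @param n size of set 2.
#' @param N universe size (features quantified in both analyses).
#' @return object of class `OverlapStat`: list with `k`, `K`, `n`, `N`,
#'   `rf`, `p` (upper tail), `log_p`, `p_point`.
#' @export
#' @examples
#' hypergeom_overlap(219, 717, 444, 4408)
hypergeom_overlap <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) stop("set sizes K and n cannot exceed the universe N")
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n) = ", min(K, n))
  if (k < max(0, K + n - N)) {
    stop("overlap k below the feasible minimum max(0, K + n - N)")
  }

  i <- k:min(K, n)
  lterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  log_p <- min(logsumexp(lterms), 0)
  structure(list(k = k, K = K, n = n, N = N,
                 rf = if (K > 0 && n > 0) k * N / (K * n) else NA_real_,
                 p = exp(log_p),
                 log_p = log_p,
                 p_point = exp(lterms[1])),
            class = "OverlapStat")
}

#' @export
print.OverlapStat <- function(x, ...) {
  cat(sprintf("Overlap %d of (K=%d, n=%d) in universe N=%d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  RF = %.3g, P(X >= k) = %.3g (log %.4f), P(X = k) = %.3g\n",
              x$rf, x$p, x$log_p, x$p_point))
  invisible(x)
}

#' @export
as.data.frame.OverlapStat <- function(x, ...) {
  data.frame(k = x$k, K = x$K, n = x$n, N = x$N, rf = x$rf, p = x$p,
             log_p = x$log_p, p_point = x$p_point)
}

#' Overlap statistic for two regulated feature sets
#'
#' Convenience wrapper counting the intersection of two id vectors inside a
#' declared universe before delegating to [hypergeom_overlap()].
#'
#' @param set1,set2 character vectors of feature ids.
#' @param universe character vector of all features eligible for both sets.
#' @return `OverlapStat`.
#' @export
overlap_sets <- function(set1, set2, universe) {
  set1 <- intersect(unique(set1), universe)
  set2 <- intersect(unique(set2), universe)
  hypergeom_overlap(length(intersect(set1, set2)), length(set1),
                    length(set2), length(universe))
}
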