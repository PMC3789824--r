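#' Exact achieved power of the Fisher test for two proportions
#'
#' Enumerates the joint distribution of carrier counts `k1 ~ Binomial(n1,
#' p1)` and `k2 ~ Binomial(n2, p2)` and accumulates the probability of
#' the outcomes in which the Fisher exact test on the realized 2x2 table
#' rejects at level `alpha` (rejection at p <= alpha, inclusive).
#' Hypergeometric point probabilities are computed in log space; binomial
#' outcomes with probability below `trunc` are skipped, so the absolute
#' truncation error of the reported power is bounded by
#' `(n1 + 1) * (n2 + 1) * trunc` plus the mass of the two discarded
#' binomial tails (both negligible at the default 1e-12).
#'
#' @param n1,n2 group sizes.
#' @param p1,p2 true carrier proportions (in (0, 1)).
#' @param alpha significance level (default 0.05).
#' @param tails "two" for the two-tailed test, "one" for the one-tailed
#'   test in the enrichment direction (proportion 1 greater than
#'   proportion 2).
#' @param trunc binomial tail truncation threshold (default 1e-12).
#' @return achieved power in [0, 1].
#' @export
fisher_exact_power <- function(n1, n2, p1, p2, alpha = 0.05,
                               tails = c("two", "one"), trunc = 1e-12) {
  tails <- match.arg(tails)
  stopifnot(n1 >= 1, n2 >= 1, p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            alpha > 0, alpha < 1)
  w1 <- dbinom(0:n1, n1, p1)
  w2 <- dbinom(0:n2, n2, p2)
  k1s <- which(w1 > trunc) - 1L
  k2s <- which(w2 > trunc) - 1L
  if (!length(k1s) || !length(k2s)) stop("infeasible power specification")
  pfun <- if (tails == "two") fisher_two_tailed else fisher_one_tailed
  power <- 0
  for (k1 in k1s) {
    for (k2 in k2s) {
      # the k1 = k2 = 0 corner is a zero-margin table (p = 1, never rejects)
      p <- suppressWarnings(pfun(k1, n1 - k1, k2, n2 - k2))
      if (p <= alpha) power <- power + w1[k1 + 1L] * w2[k2 + 1L]
    }
  }
  power
}
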