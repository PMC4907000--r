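#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the point-probability (minimum-likelihood)
#' convention: the sum of hypergeometric probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed table.
#' Used to compare out-of-frame read abundance between two samples.
#'
#' @param a,b,c,d cell counts (row 1: `a`, `b`; row 2: `c`, `d`), or a 2x2
#'   matrix passed as `a`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  if (sum(m) == 0) stop("at least one margin must be positive")
  stats::fisher.test(m)$p.value
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that two sets
#' of sizes `K` and `n`, drawn from a universe of `N` items, share at least
#' `k` items by chance. Evaluated in log space, so universes as large as the
#' ~1e8 unique CDR3 amino-acid variants are handled without underflow.
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param k observed overlap.
#' @return the p-value.
#' @export
hypergeom_overlap_test <- function(N, K, n, k) {
  if (K > N || n > N) stop("set sizes cannot exceed the universe size")
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)")
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Compare out-of-frame read abundance between two samples
#'
#' Builds the 2x2 contingency table of out-of-frame vs in-frame read counts
#' for two samples and applies [fisher_exact_2x2()].
#'
#' @param table_a,table_b [clonotype_table()]s.
#' @return list with the contingency `table` (2x2 matrix) and `p_value`.
#' @export
compare_oof <- function(table_a, table_b) {
  tally <- function(t) {
    oof <- t$frame == "out"
    c(sum(t$count[oof]), sum(t$count[!oof]))
  }
  m <- rbind(tally(table_a), tally(table_b))
  dimnames(m) <- list(c(attr(table_a, "sample_id"),
                        attr(table_b, "sample_id")),
                      c("out_of_frame", "in_frame"))
  list(table = m, p_value = fisher_exact_2x2(m))
}
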