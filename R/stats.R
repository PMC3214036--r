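# 2x2 tests and multiple-testing adjustment used by every enrichment
# contrast. Tables are count matrices with rows = in-class / not-in-class and
# columns = has-term / lacks-term.

as_counts_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    x <- as.numeric(t(table))
  } else {
    x <- as.numeric(table)
    stopifnot(length(x) == 4)
  }
  if (anyNA(x) || any(x < 0)) {
    abort("2x2 table must hold non-negative counts")
  }
  if (any(x != floor(x))) {
    abort("2x2 table must hold integer counts")
  }
  setNames(x, c("a", "b", "c", "d"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided conditional test: with all margins fixed, the p-value is the
#' sum of hypergeometric probabilities of every table at least as extreme as
#' (i.e. with point probability no larger than) the observed one. The
#' reported odds ratio is the sample estimate `ad/bc`: 0 when `a` or `d` is
#' zero, `Inf` when `b` or `c` is zero (with a non-zero numerator), `NA`
#' when the estimate is 0/0.
#'
#' @param table A 2x2 count matrix, or a length-4 vector `(a, b, c, d)` read
#'   row-wise.
#' @return A tibble with columns `odds_ratio`, `p_value`, `a`, `b`, `c`, `d`.
#' @examples
#' fisher_2x2(matrix(c(3, 7, 7, 83), nrow = 2, byrow = TRUE))
#' @export
fisher_2x2 <- function(table) {
  x <- as_counts_2x2(table)
  a <- x[["a"]]; b <- x[["b"]]; c_ <- x[["c"]]; d <- x[["d"]]
  m <- a + b        # row-1 margin
  n_ <- c_ + d      # row-2 margin
  k <- a + c_       # column-1 margin
  if (m + n_ == 0 || k == 0 || k == m + n_ || m == 0 || n_ == 0) {
    # a degenerate margin: only one table is possible
    p <- 1
  } else {
    lo <- max(0, k - n_)
    hi <- min(k, m)
    support <- lo:hi
    probs <- dhyper(support, m, n_, k)
    p_obs <- dhyper(a, m, n_, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-07)])
    p <- min(1, p)
  }
  or <- if (a * d == 0 && b * c_ == 0) {
    NA_real_
  } else if (b * c_ == 0) {
    Inf
  } else {
    (a * d) / (b * c_)
  }
  tibble::new_tibble(list(odds_ratio = unname(or), p_value = unname(p),
                          a = a, b = b, c = c_, d = d), nrow = 1L)
}

#' Pearson chi-square test for a 2x2 table
#'
#' One-degree-of-freedom test of independence, optionally with the Yates
#' continuity correction (off by default; the tables this pipeline tests are
#' large). Errors when any expected count is zero — use [fisher_2x2()] then.
#'
#' @inheritParams fisher_2x2
#' @param continuity_correction Apply the Yates correction.
#' @return A tibble with columns `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  x <- as_counts_2x2(table)
  mat <- matrix(x, nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  if (any(expected == 0)) {
    abort("zero expected count in 2x2 table; use fisher_2x2() instead")
  }
  ht <- suppressWarnings(chisq.test(mat, correct = continuity_correction))
  tibble(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
         df = unname(ht$parameter))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: after sorting ascending, `q(i) = min over j >= i of
#' p(j) * m / j`, capped at 1, returned in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric())
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Compare two degree sequences
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum and two-sample
#' Kolmogorov-Smirnov tests, as used to compare the connectivity of gene
#' groups in a protein-protein interaction network.
#'
#' @param seq1,seq2 Non-empty numeric vectors (typically node degrees).
#' @return A tibble with one row per test: `method`, `statistic`, `p_value`.
#' @export
compare_degree_distributions <- function(seq1, seq2) {
  if (length(seq1) == 0 || length(seq2) == 0) {
    abort("degree sequences must be non-empty")
  }
  w <- suppressWarnings(wilcox.test(seq1, seq2, alternative = "two.sided"))
  k <- suppressWarnings(ks.test(seq1, seq2, alternative = "two.sided"))
  tibble(
    method = c("wilcoxon_mann_whitney", "kolmogorov_smirnov"),
    statistic = c(unname(w$statistic), unname(k$statistic)),
    p_value = c(w$p.value, k$p.value)
  )
}
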