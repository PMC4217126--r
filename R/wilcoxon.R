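# Rank-sum p-value for one feature. W is the Mann-Whitney U of group 2
# (rank sum of group 2 minus n2*(n2+1)/2). Exact distribution (stats::pwilcox)
# when there are no ties and the combined n is small; otherwise normal
# approximation with tie correction and continuity correction, mirroring the
# classical large-sample formula.
rank_sum_p <- function(w, n1, n2, tie_counts, exact,
                       alternative = c("two.sided", "greater", "less"),
                       continuity = TRUE) {
  alternative <- match.arg(alternative)
  if (exact) {
    # pwilcox is the distribution of U for the FIRST sample; by symmetry
    # U2 ~ Wilcoxon(n2, n1)
    switch(alternative,
      two.sided = {
        pp <- if (w > n1 * n2 / 2) 1 - stats::pwilcox(w - 1, n2, n1)
              else stats::pwilcox(w, n2, n1)
        min(2 * pp, 1)
      },
      greater = 1 - stats::pwilcox(w - 1, n2, n1),
      less = stats::pwilcox(w, n2, n1))
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z_num <- w - mu
    cc <- if (continuity)
      switch(alternative, two.sided = sign(z_num) * 0.5, greater = 0.5, less = -0.5)
    else 0
    z <- (z_num - cc) / sqrt(sigma2)
    switch(alternative,
      two.sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
  }
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-feature two-group rank-sum test. The exact null distribution is used
#' when the combined sample size is at most `exact_max` and the feature has
#' no ties; otherwise the normal approximation with tie and continuity
#' correction. Two-sided by default.
#'
#' @param mat an [expression_matrix()] with exactly two groups, each n >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` (group2 > group1)
#'   or `"less"`.
#' @param exact_max maximum combined n for the exact path (default 12).
#' @return data frame of class `de_table` with columns `feature_id`, `mean1`,
#'   `mean2`, `log2_fc`, `W_stat` (Mann-Whitney U of group 2), `p`, `q`.
#' @export
wilcoxon_de <- function(mat, alternative = c("two.sided", "greater", "less"),
                        exact_max = 12L) {
  alternative <- match.arg(alternative)
  idx <- two_group_index(mat)
  x <- mat$values
  i1 <- idx[[1L]]; i2 <- idx[[2L]]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  n <- n1 + n2
  res <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, c(i1, i2)]
    r <- rank(v)
    w <- sum(r[(n1 + 1L):n]) - n2 * (n2 + 1L) / 2
    ties <- table(v)
    exact <- n <= exact_max && all(ties == 1L)
    c(w, rank_sum_p(w, n1, n2, as.numeric(ties), exact, alternative))
  }, numeric(2L))
  p <- pmin(res[2L, ], 1)
  out <- data.frame(feature_id = rownames(x),
                    mean1 = m1, mean2 = m2, log2_fc = m2 - m1,
                    W_stat = res[1L, ], p = p, q = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}
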