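#' Delta-delta-Ct relative quantification
#'
#' For each target gene and sample: `dCt_s = Ct_target,s - Ct_ref,s`;
#' `ddCt_s = dCt_s - mean(dCt over control-group samples)`; per-sample fold
#' `2^(-ddCt_s)` (amplification efficiency fixed at 2). Group summaries
#' report the fold of the mean, `2^(-mean ddCt)` — exactly 1 for the control
#' group by construction — with the s.e.m. computed on the per-sample fold
#' values.
#'
#' @param ct a [ct_table()].
#' @return list with `samples` (per-sample `dct`, `ddct`, `fold`) and
#'   `groups` (per gene x group `mean_ddct`, `fold`, `sem_fold`, `n`), both
#'   plain data frames.
#' @export
delta_delta_ct <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference_gene")
  ctrl <- attr(ct, "control_group")
  ref_ct <- ct$ct[ct$gene == ref]
  names(ref_ct) <- ct$sample_id[ct$gene == ref]
  tg <- ct[ct$gene != ref, , drop = FALSE]
  if (!nrow(tg)) stop("no target-gene measurements")
  tg$dct <- tg$ct - ref_ct[tg$sample_id]
  out <- do.call(rbind, lapply(split(tg, tg$gene), function(d) {
    ctrl_mean <- mean(d$dct[d$group == ctrl])
    if (!is.finite(ctrl_mean))
      stop("control group has no measurements for gene ", d$gene[1L])
    d$ddct <- d$dct - ctrl_mean
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  grp <- do.call(rbind, lapply(split(out, list(out$gene, out$group), drop = TRUE),
    function(d) data.frame(gene = d$gene[1L], group = d$group[1L],
                           n = nrow(d), mean_ddct = mean(d$ddct),
                           fold = 2^(-mean(d$ddct)),
                           sem_fold = stats::sd(d$fold) / sqrt(nrow(d)),
                           stringsAsFactors = FALSE)))
  grp <- grp[order(grp$gene, grp$group), , drop = FALSE]
  rownames(grp) <- NULL
  list(samples = out[c("sample_id", "group", "gene", "ct", "dct", "ddct", "fold")],
       groups = grp)
}

#' Two-tailed two-sample Student t-test
#'
#' Equal-variance by default; Welch behind a flag. If the pooled variance is
#' zero with equal means, returns `t = 0, p = 1`; with unequal means this is
#' an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (classical Student t, default).
#' @return list with `t`, `df`, `p`.
#' @export
ttest_two_tailed <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    stop("zero variance in both groups with unequal means; t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post test
#'
#' Fixed-effects one-way ANOVA over three or more groups, followed by all
#' pairwise equal-variance two-sample t-tests with p-values multiplied by the
#' number of comparisons (capped at 1).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`, and `pairwise` (data frame
#'   `group1`, `group2`, `p_raw`, `p_bonferroni`).
#' @export
oneway_anova_bonferroni <- function(groups) {
  if (length(groups) < 3L)
    stop("fewer than 3 groups; use ttest_two_tailed() for two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  if (is.nan(f)) f <- 0  # zero between- and within-group variation
  pr <- utils::combn(names(groups), 2L)
  m <- ncol(pr)
  pairwise <- do.call(rbind, lapply(seq_len(m), function(k) {
    tt <- ttest_two_tailed(groups[[pr[1L, k]]], groups[[pr[2L, k]]])
    data.frame(group1 = pr[1L, k], group2 = pr[2L, k], p_raw = tt$p,
               p_bonferroni = min(1, tt$p * m), stringsAsFactors = FALSE)
  }))
  list(F = f, df1 = unname(fit$parameter[1L]), df2 = unname(fit$parameter[2L]),
       p = if (is.nan(fit$p.value)) 1 else fit$p.value, pairwise = pairwise)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction by default (`yates = TRUE` enables it for 2x2
#' tables). Errors if any expected cell count is zero.
#'
#' @param tab matrix of non-negative counts.
#' @param yates apply the Yates continuity correction (2x2 only).
#' @return list with `chi2`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero; test undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = expected)
}
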