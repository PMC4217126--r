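# Newton inversion of the trigamma function, used by the empirical-Bayes
# moment fit. Monotone decreasing on (0, Inf); standard starting value 0.5 + 1/x.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1L))
}

# Moment fit of a scaled F prior to residual sample variances s2 on df degrees
# of freedom: log s2 is matched to the sum of two log-chi-square terms, giving
# prior df d0 and prior variance s0^2. Features with zero variance are
# excluded from the fit (they carry no information about the scatter of s2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(d0 = Inf, s02 = if (any(ok)) mean(s2[ok]) else 0))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess scatter in s2 beyond chi-square sampling noise: variances are
    # fully pooled
    d0 <- Inf
    s02 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' For each feature the pooled two-group variance `s^2` (on `d_res = n1+n2-2`
#' degrees of freedom) is shrunk toward a common prior fitted across
#' features by moment matching on `log s^2`:
#' `s_post^2 = (d0*s0^2 + d_res*s^2) / (d0 + d_res)`. The moderated statistic
#' is `t = (mean2 - mean1) / (s_post * sqrt(1/n1 + 1/n2))` referred to a t
#' distribution on `d0 + d_res` degrees of freedom; q-values are
#' Benjamini-Hochberg adjusted p-values.
#'
#' If the prior fit is degenerate (non-finite `d0`, e.g. essentially constant
#' variances) the test falls back to fully pooled variance (`d0 = Inf`) with a
#' warning. A matrix with zero variance everywhere is handled as the
#' noise-free limit: `t = 0, p = 1` where the group means are equal and
#' `t = +/-Inf, p = 0` where they differ.
#'
#' @param mat an [expression_matrix()] with exactly two groups, each n >= 2,
#'   on the log2 scale.
#' @param prior_df optional override of the prior degrees of freedom `d0`;
#'   `0` gives the ordinary equal-variance Student t, `Inf` the fully pooled
#'   t. Default `NULL` fits `d0` from the data.
#' @param prior_var optional override of the prior variance `s0^2`; only used
#'   with a finite, positive `prior_df`.
#' @return data frame of class `de_table` with columns `feature_id`,
#'   `mean1`, `mean2`, `log2_fc`, `t_stat`, `df`, `p`, `q`, plus attributes
#'   `d0` and `s02`.
#' @export
moderated_t <- function(mat, prior_df = NULL, prior_var = NULL) {
  idx <- two_group_index(mat)
  x1 <- mat$values[, idx[[1L]], drop = FALSE]
  x2 <- mat$values[, idx[[2L]], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  d_res <- n1 + n2 - 2L
  s2 <- ss / d_res

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d_res)
    d0 <- fit$d0; s02 <- fit$s02
    if (!is.finite(d0)) {
      # moment fit found no excess scatter in s2; fully pooled variance
      d0 <- Inf
    }
  } else {
    d0 <- prior_df
    s02 <- if (is.null(prior_var)) mean(s2) else prior_var
  }

  s2_post <- if (is.infinite(d0)) {
    rep.int(if (is.null(prior_var)) s02 else prior_var, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d_res * s2) / (d0 + d_res)
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  t_stat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  # total df capped at the pooled residual df across all features
  df_total <- min(d0 + d_res, d_res * length(s2))
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p[t_stat == 0] <- 1
  out <- data.frame(feature_id = rownames(mat$values),
                    mean1 = m1, mean2 = m2, log2_fc = delta,
                    t_stat = t_stat, df = rep_len(df_total, length(p)),
                    p = p, q = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
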