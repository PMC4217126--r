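# All two-group label assignments (columns = indices of the samples placed in
# group 2). Enumerated exhaustively when choose(n, n2) <= cap, otherwise a
# seeded random sample of n_perm assignments.
permutation_assignments <- function(n, n2, n_perm, cap = 10000L, seed = NULL) {
  total <- choose(n, n2)
  if (total <= cap) {
    list(idx = utils::combn(n, n2), enumerated = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- replicate(n_perm, sort(sample.int(n, n2)))
    list(idx = idx, enumerated = FALSE)
  }
}

# d and s for an arbitrary assignment of columns to group 2.
sam_d_stat <- function(x, g2, s0) {
  g1 <- setdiff(seq_len(ncol(x)), g2)
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
        rowSums((x[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2L))
  list(d = (m2 - m1) / (s + s0), s = s, r = m2 - m1)
}

# d statistics for every assignment at once (assignments = columns of idx,
# each holding the sample indices placed in group 2). One matrix product
# yields all group-2 sums; the pooled within-group sum of squares follows
# from sum(x) and sum(x^2) per feature.
sam_d_all <- function(x, idx, s0) {
  n <- ncol(x); n2 <- nrow(idx); n1 <- n - n2
  K <- ncol(idx)
  P <- matrix(0, n, K)
  P[cbind(as.vector(idx), rep(seq_len(K), each = n2))] <- 1
  S2 <- x %*% P
  sumx <- rowSums(x); sumx2 <- rowSums(x^2)
  m2 <- S2 / n2
  m1 <- (sumx - S2) / n1
  ss <- pmax(sumx2 - n1 * m1^2 - n2 * m2^2, 0)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2L))
  (m2 - m1) / (s + s0)
}

# Tusher-style exchangeability constant: over a grid of candidate s0 values
# (percentiles of s), pick the one minimizing the coefficient of variation of
# the median absolute d across windows of features grouped by s percentile.
choose_s0 <- function(r, s, s0_grid = NULL) {
  if (is.null(s0_grid)) s0_grid <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05)))
  if (all(s0_grid == 0) || all(!is.finite(s0_grid)))
    stop("all features have zero scatter; supply a nonzero 's0_grid'")
  n_win <- max(2L, min(100L, floor(length(s) / 5)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(s0_grid, function(a) {
    d <- r / (s + a)
    v <- tapply(abs(d - stats::median(d)), win, stats::median)
    if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
  }, numeric(1L))
  if (all(!is.finite(cv))) {
    pos <- s0_grid[s0_grid > 0]
    if (!length(pos)) stop("all features have zero scatter; supply a nonzero 's0_grid'")
    return(min(pos))
  }
  s0_grid[which.min(cv)]
}

# FDR machinery: thresholds for a given delta from the sorted observed d
# versus the expected (null) order statistics dbar.
sam_cutoffs <- function(d_sorted, dbar, delta) {
  up_idx <- which(d_sorted - dbar >= delta & d_sorted > 0)
  low_idx <- which(dbar - d_sorted >= delta & d_sorted < 0)
  list(cut_up = if (length(up_idx)) d_sorted[min(up_idx)] else Inf,
       cut_low = if (length(low_idx)) d_sorted[max(low_idx)] else -Inf)
}

#' Two-class unpaired SAM with permutation-estimated FDR
#'
#' Significance analysis of microarrays for a two-group design. The relative
#' difference for feature i is `d_i = (mean2 - mean1) / (s_i + s0)` where
#' `s_i` is the pooled standard error of the difference and the
#' exchangeability constant `s0` is chosen over a percentile grid of `s` to
#' minimize the coefficient of variation of the scatter of `d` across `s`
#' windows. Expected order statistics come from two-group label permutations
#' (exhaustive when the total count is at most `enum_cap`, otherwise `n_perm`
#' seeded random assignments). The threshold `delta` is the smallest value on
#' the candidate grid whose estimated FDR is at most `target_fdr`; features
#' beyond the resulting asymmetric cutoffs are called up or down.
#'
#' The FDR at a threshold is `pi0 * median(# null d beyond the cutoffs) /
#' (# features called)`, with `pi0 = min(1, 2 * fraction of observed d inside
#' the central 50% of the permutation null d)`.
#'
#' @param mat an [expression_matrix()] with exactly two groups, each n >= 2.
#' @param n_perm number of random permutations when exhaustive enumeration is
#'   not feasible.
#' @param target_fdr desired median false discovery rate (default 0.01).
#' @param seed integer seed for permutation sampling (ignored when the full
#'   set is enumerated).
#' @param s0_grid optional numeric vector of candidate `s0` values; defaults
#'   to the 0,5,...,100 percentiles of `s`. Required nonzero when every
#'   feature has zero scatter.
#' @param enum_cap largest permutation count that is enumerated exhaustively.
#' @param delta optional fixed threshold; skips the delta search.
#' @return object of class `sam_result`: list with `table` (feature_id, d, s,
#'   dbar, call), `s0`, `delta`, `cut_up`, `cut_low`, `estimated_fdr`, `pi0`,
#'   `n_perm`, `enumerated`, `up`, `down`.
#' @export
sam_two_class <- function(mat, n_perm = 1000L, target_fdr = 0.01, seed = NULL,
                          s0_grid = NULL, enum_cap = 10000L, delta = NULL) {
  idx <- two_group_index(mat)
  x <- mat$values
  obs_g2 <- idx[[2L]]
  n <- ncol(x); n2 <- length(obs_g2)

  base <- sam_d_stat(x, obs_g2, s0 = 0)
  s0 <- choose_s0(base$r, base$s, s0_grid)
  d <- base$r / (base$s + s0)

  perms <- permutation_assignments(n, n2, n_perm, cap = enum_cap, seed = seed)
  d_null <- sam_d_all(x, perms$idx, s0)
  null_sorted <- apply(d_null, 2L, sort)
  if (is.null(dim(null_sorted))) null_sorted <- matrix(null_sorted, nrow = 1L)
  dbar <- rowMeans(null_sorted)

  ord <- order(d)
  d_sorted <- d[ord]
  qs <- stats::quantile(as.vector(null_sorted), c(0.25, 0.75))
  pi0 <- min(1, 2 * mean(d >= qs[1L] & d <= qs[2L]))

  eval_delta <- function(dl) {
    cuts <- sam_cutoffs(d_sorted, dbar, dl)
    called <- d >= cuts$cut_up | d <= cuts$cut_low
    n_called <- sum(called)
    if (n_called == 0L) return(list(fdr = 0, cuts = cuts, called = called))
    null_called <- colSums(null_sorted >= cuts$cut_up) +
                   colSums(null_sorted <= cuts$cut_low)
    list(fdr = min(1, pi0 * stats::median(null_called) / n_called),
         cuts = cuts, called = called)
  }

  if (is.null(delta)) {
    cand <- sort(unique(abs(d_sorted - dbar)))
    delta <- NA_real_
    res <- NULL
    for (dl in cand) {
      r <- eval_delta(dl)
      if (r$fdr <= target_fdr) { delta <- dl; res <- r; break }
    }
    if (is.null(res)) { delta <- Inf; res <- eval_delta(Inf) }
  } else {
    res <- eval_delta(delta)
  }

  call <- rep("ns", length(d))
  call[res$called & d > 0] <- "up"
  call[res$called & d < 0] <- "down"
  dbar_feature <- numeric(length(d))
  dbar_feature[ord] <- dbar
  tab <- data.frame(feature_id = rownames(x), d = d, s = base$s,
                    dbar = dbar_feature,
                    call = factor(call, levels = c("up", "down", "ns")),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = s0, delta = delta,
                 cut_up = res$cuts$cut_up, cut_low = res$cuts$cut_low,
                 estimated_fdr = res$fdr, pi0 = pi0,
                 n_perm = ncol(null_sorted), enumerated = perms$enumerated,
                 up = tab$feature_id[tab$call == "up"],
                 down = tab$feature_id[tab$call == "down"]),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("sam_result: ", nrow(x$table), " features; s0 = ", signif(x$s0, 4),
      "; delta = ", signif(x$delta, 4), "\n", sep = "")
  cat("calls: ", length(x$up), " up, ", length(x$down), " down; estimated FDR ",
      signif(x$estimated_fdr, 3), " (pi0 = ", signif(x$pi0, 3), ")\n", sep = "")
  invisible(x)
}
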