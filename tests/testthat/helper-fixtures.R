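# Shared fixture builders for the test suite; everything is generated in
# code, nothing is read from disk.

# Small two-group expression matrix from explicit per-group value matrices.
toy_matrix <- function(g1, g2, feature_ids = NULL,
                       levels = c("control", "treated")) {
  stopifnot(nrow(g1) == nrow(g2))
  vals <- cbind(g1, g2)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(vals)))
  rownames(vals) <- feature_ids
  colnames(vals) <- c(paste0("c", seq_len(ncol(g1))), paste0("t", seq_len(ncol(g2))))
  groups <- stats::setNames(rep(levels, c(ncol(g1), ncol(g2))), colnames(vals))
  expression_matrix(vals, groups, group_levels = levels)
}

# Null (no-effect) Gaussian matrix.
null_matrix <- function(n_features, n_per_group, sd = 0.25, seed = 1L) {
  set.seed(seed)
  toy_matrix(matrix(rnorm(n_features * n_per_group, 8, sd), n_features),
             matrix(rnorm(n_features * n_per_group, 8, sd), n_features))
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1L)),
    sprintf("g%04d", seq_len(n)))
}

# Independent brute-force substring finder: checks every position.
naive_find <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  if (L < k) return(integer(0L))
  starts <- seq_len(L - k + 1L)
  starts[substring(seq, starts, starts + k - 1L) == pattern] - 1L  # 0-based
}

# Exhaustive two-group label enumeration oracle for the rank-sum test.
# Returns one- and two-sided p for the observed assignment (first n1 = group1).
enum_rank_sum <- function(x1, x2) {
  v <- c(x1, x2)
  n <- length(v); n1 <- length(x1); n2 <- length(x2)
  r <- rank(v)
  u_obs <- sum(r[(n1 + 1L):n]) - n2 * (n2 + 1L) / 2
  combs <- utils::combn(n, n2)
  u_all <- apply(combs, 2L, function(g2) sum(r[g2]) - n2 * (n2 + 1L) / 2)
  p_ge <- mean(u_all >= u_obs)
  p_le <- mean(u_all <= u_obs)
  list(u = u_obs, p_greater = p_ge, p_less = p_le,
       p_two = min(1, 2 * min(p_ge, p_le)))
}

# Plain-loop d statistic for the SAM oracle (independent of the package's
# vectorized path).
naive_sam_d <- function(x, g2_cols, s0) {
  g1_cols <- setdiff(seq_len(ncol(x)), g2_cols)
  d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- x[i, g1_cols]; b <- x[i, g2_cols]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / length(a) + 1 / length(b)) * ss / (length(a) + length(b) - 2))
    d[i] <- (mean(b) - mean(a)) / (s + s0)
  }
  d
}
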