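test_that("moderated t with no shrinkage equals the ordinary Student t", {
  set.seed(11)
  mat <- toy_matrix(matrix(rnorm(30, 8), 10), matrix(rnorm(30, 8.5), 10))
  res <- moderated_t(mat, prior_df = 0)
  for (i in c(1, 5, 10)) {
    tt <- t.test(mat$values[i, 4:6], mat$values[i, 1:3], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t matches the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  mat <- toy_matrix(matrix(rnorm(500 * 4, 8, 0.4), 500),
                    matrix(rnorm(500 * 4, 8, 0.4), 500))
  res <- moderated_t(mat)
  design <- cbind(1, rep(0:1, each = 4))
  fit <- limma::eBayes(limma::lmFit(mat$values, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("zero mean difference gives t = 0 and p = 1 regardless of shrinkage", {
  g <- matrix(c(1, 2, 3, 5, 6, 9), 2, 3, byrow = TRUE)
  mat <- toy_matrix(g, g)
  for (d0 in list(0, 3, NULL)) {
    res <- moderated_t(mat, prior_df = d0)
    expect_equal(res$t_stat, c(0, 0))
    expect_equal(res$p, c(1, 1))
  }
})

test_that("exact Wilcoxon path reproduces enumeration and wilcox.test", {
  # canonical complete-separation case: one of C(6,3)=20 orderings
  mat <- toy_matrix(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  res <- wilcoxon_de(mat, alternative = "greater")
  expect_equal(res$p, 0.05)
  oracle <- enum_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, oracle$p_greater)
  # identical groups: p = 1
  same <- toy_matrix(matrix(1:4, 1), matrix(1:4, 1))
  expect_equal(wilcoxon_de(same)$p, 1)
  # random 4v4 data without ties: exact path equals all-70-assignment oracle
  set.seed(21)
  for (rep in 1:20) {
    x1 <- rnorm(4); x2 <- rnorm(4)
    mat <- toy_matrix(matrix(x1, 1), matrix(x2, 1))
    res <- wilcoxon_de(mat)
    oracle <- enum_rank_sum(x1, x2)
    expect_equal(res$p, oracle$p_two)
    ref <- wilcox.test(x2, x1, exact = TRUE)
    expect_equal(res$p, ref$p.value)
    expect_equal(res$W_stat, unname(ref$statistic))
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  x1 <- c(1, 1, 2, 3, 3, 4, 9); x2 <- c(2, 3, 3, 5, 5, 6, 7)
  mat <- toy_matrix(matrix(x1, 1), matrix(x2, 1))
  ref <- suppressWarnings(wilcox.test(x2, x1, exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_de(mat)$p, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(31)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12 & q <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("SAM d statistic is zero for equal group means at any s0", {
  g <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE)
  mat <- toy_matrix(g, g[, c(2, 1, 3)])
  for (s0 in c(0.1, 1)) {
    res <- sam_two_class(mat, s0_grid = s0, target_fdr = 0.05)
    expect_equal(res$table$d, c(0, 0))
  }
})

test_that("SAM estimated FDR on a 3v3 toy equals the brute-force enumeration", {
  set.seed(41)
  vals <- rbind(matrix(rnorm(60, 8, 0.3), 10),
                cbind(matrix(rnorm(15, 8, 0.3), 5),
                      matrix(rnorm(15, 10, 0.3), 5)))
  mat <- toy_matrix(vals[, 1:3], vals[, 4:6])
  res <- sam_two_class(mat, target_fdr = 0.1, s0_grid = 0.2)
  expect_true(res$enumerated)
  expect_equal(res$n_perm, choose(6, 3))
  # independent recount: plain-loop d over every assignment
  combs <- combn(6, 3)
  null_counts <- apply(combs, 2, function(g2) {
    dn <- naive_sam_d(mat$values, g2, s0 = res$s0)
    sum(dn >= res$cut_up | dn <= res$cut_low)
  })
  d_obs <- naive_sam_d(mat$values, 4:6, s0 = res$s0)
  n_called <- sum(d_obs >= res$cut_up | d_obs <= res$cut_low)
  qs <- quantile(as.vector(sapply(seq_len(ncol(combs)), function(k)
    naive_sam_d(mat$values, combs[, k], s0 = res$s0))), c(0.25, 0.75))
  pi0 <- min(1, 2 * mean(d_obs >= qs[1] & d_obs <= qs[2]))
  expect_equal(res$pi0, pi0)
  expect_equal(res$estimated_fdr,
               min(1, pi0 * median(null_counts) / n_called))
  expect_equal(length(res$up) + length(res$down), n_called)
})

test_that("SAM is deterministic under a fixed seed when sampling permutations", {
  set.seed(51)
  mat <- null_matrix(50, 8, sd = 0.3, seed = 51)
  r1 <- sam_two_class(mat, n_perm = 50, seed = 99, enum_cap = 10, target_fdr = 0.1)
  r2 <- sam_two_class(mat, n_perm = 50, seed = 99, enum_cap = 10, target_fdr = 0.1)
  expect_false(r1$enumerated)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$estimated_fdr, r2$estimated_fdr)
})

test_that("SAM errors on all-zero scatter unless a nonzero s0 grid is supplied", {
  g1 <- matrix(rep(c(8, 5), each = 3), 2, 3, byrow = TRUE)
  mat <- toy_matrix(g1, g1 + c(1, 0))
  expect_error(sam_two_class(mat), "s0_grid")
  res <- sam_two_class(mat, s0_grid = 0.5, target_fdr = 0.05)
  expect_identical(res$up, "f1")
})

test_that("fold-change and p thresholds are inclusive and symmetric", {
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   log2_fc = c(0.585, 0.3, -0.585, -2),
                   p = c(0.049, 0.001, 0.05, 0.2),
                   q = c(0.1, 0.01, 0.1, 0.4))
  out <- threshold_de(de, fc_min = 1.5, p_max = 0.05)
  expect_identical(as.character(out$call), c("up", "ns", "down", "ns"))
  # q-gating switches the significance column
  outq <- threshold_de(de, fc_min = 1.5, p_max = 0.05, use_q = TRUE)
  expect_identical(as.character(outq$call), c("ns", "ns", "ns", "ns"))
  # sign flip swaps the up and down sets exactly
  flip <- de; flip$log2_fc <- -flip$log2_fc
  out2 <- threshold_de(flip, fc_min = 1.5, p_max = 0.05)
  expect_identical(out2$feature_id[out2$call == "up"],
                   out$feature_id[out$call == "down"])
  expect_identical(out2$feature_id[out2$call == "down"],
                   out$feature_id[out$call == "up"])
  expect_error(threshold_de(de, fc_min = 1), "exceed 1")
})
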