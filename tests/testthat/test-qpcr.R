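make_ct <- function(ct_ctrl_target, ct_ctrl_ref, ct_trt_target, ct_trt_ref) {
  n1 <- length(ct_ctrl_target); n2 <- length(ct_trt_target)
  samples <- c(paste0("c", seq_len(n1)), paste0("t", seq_len(n2)))
  group <- rep(c("ctrl", "trt"), c(n1, n2))
  ct_table(data.frame(
    sample_id = rep(samples, 2), group = rep(group, 2),
    gene = rep(c("tgt", "ref"), each = n1 + n2),
    ct = c(ct_ctrl_target, ct_trt_target, ct_ctrl_ref, ct_trt_ref)),
    reference_gene = "ref", control_group = "ctrl")
}

test_that("delta-delta-Ct reproduces hand arithmetic and its invariances", {
  # control (Ct_t 25, Ct_ref 20), treated (Ct_t 24, Ct_ref 20): fold = 2
  ct <- make_ct(c(25, 25), c(20, 20), c(24, 24), c(20, 20))
  res <- delta_delta_ct(ct)
  trt <- res$groups[res$groups$group == "trt", ]
  expect_equal(trt$mean_ddct, -1)
  expect_equal(trt$fold, 2)
  ctrl <- res$groups[res$groups$group == "ctrl", ]
  expect_equal(ctrl$fold, 1)  # control mean fold is 1 by construction
  # equal dCt in both groups -> fold 1 everywhere
  same <- delta_delta_ct(make_ct(c(25, 26), c(20, 21), c(24.5, 25.5), c(19.5, 20.5)))
  expect_equal(same$groups$fold, c(1, 1))
  # shifting every Ct of one sample by +c leaves its fold unchanged
  shifted <- make_ct(c(25, 25), c(20, 20), c(24 + 3, 24), c(20 + 3, 20))
  expect_equal(delta_delta_ct(shifted)$samples$fold,
               delta_delta_ct(ct)$samples$fold)
})

test_that("Ct table validation catches missing reference measurements", {
  bad <- data.frame(sample_id = c("s1", "s2", "s1"),
                    group = c("ctrl", "ctrl", "ctrl"),
                    gene = c("tgt", "tgt", "ref"),
                    ct = c(25, 25, 20))
  expect_error(ct_table(bad, "ref", "ctrl"), "s2")
})

test_that("two-tailed t-test matches the closed-form computation", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- ttest_two_tailed(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_direct <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_direct, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_direct), df = 4), tolerance = 1e-10)
  # symmetry and degenerate cases
  expect_equal(ttest_two_tailed(y, x)$p, res$p)
  same <- ttest_two_tailed(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(ttest_two_tailed(c(2, 2), c(3, 3)), "undefined")
})

test_that("one-way ANOVA matches direct sums of squares; Bonferroni never shrinks p", {
  g <- list(a = c(1, 2, 3), b = c(2, 4, 4), c = c(6, 7, 9))
  res <- oneway_anova_bonferroni(g)
  y <- unlist(g); k <- 3; n <- 9
  gm <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_direct <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, f_direct, tolerance = 1e-10)
  expect_equal(res$p, pf(f_direct, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_bonferroni <= 1))
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 3))
  # identical constant groups: F = 0
  flat <- oneway_anova_bonferroni(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_equal(flat$F, 0)
  expect_error(oneway_anova_bonferroni(list(a = 1:3, b = 1:3)), "two groups")
})

test_that("chi-square equals the direct O/E formula and detects no-association", {
  flat <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  set.seed(81)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- chi_square_test(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi_direct <- sum((tab - e)^2 / e)
    expect_equal(res$chi2, chi_direct, tolerance = 1e-10)
    expect_equal(res$df, 2)
    expect_equal(res$p, pchisq(chi_direct, 2, lower.tail = FALSE), tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "zero")
})

test_that("planted qPCR effects are recovered across sample sizes", {
  # zero-noise: fold exactly 2^effect
  ct0 <- generate_ct_table(effect_cycles = 1, n_per_group = 4, sd = 0, seed = 3)
  res0 <- delta_delta_ct(ct0)
  expect_equal(res0$groups$fold[res0$groups$group == "treated"], 2)
  ct_null <- generate_ct_table(effect_cycles = 0, n_per_group = 4, sd = 0, seed = 3)
  expect_equal(delta_delta_ct(ct_null)$groups$fold, c(1, 1))
  # noisy recovery: mean ddct converges toward -effect as n grows
  err <- vapply(c(3, 6, 12), function(n) {
    dd <- vapply(1:50, function(r) {
      ct <- generate_ct_table(effect_cycles = 1, n_per_group = n, sd = 0.2,
                              seed = 1000 + 13 * r + n)
      res <- delta_delta_ct(ct)
      res$groups$mean_ddct[res$groups$group == "treated"]
    }, numeric(1))
    abs(mean(dd) + 1)
  }, numeric(1))
  expect_lt(err[3], 0.15)
  folds <- 2^-vapply(1:50, function(r) {
    res <- delta_delta_ct(generate_ct_table(1, 6, 0.2, seed = 2000 + r))
    res$groups$mean_ddct[res$groups$group == "treated"]
  }, numeric(1))
  expect_lt(abs(mean(folds) / 2 - 1), 0.15)  # mean recovered fold within 15%
})
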