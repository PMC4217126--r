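test_that("reverse complement handles both alphabets and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AUGC"), "GCAU")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGX"), "invalid")
  set.seed(61)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    # agrees with the Biostrings reference
    expect_identical(reverse_complement(s),
                     as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("site patterns follow the canonical seed position rules", {
  ps24 <- build_site_patterns("miR-24", "UGGCUCAGUUCAGCAGGAACAG")
  expect_identical(ps24$seed6, "GGCUCA")
  expect_identical(unname(ps24$patterns["6mer"]), "TGAGCC")
  expect_identical(unname(ps24$patterns["7mer-m8"]), "CTGAGCC")
  expect_identical(unname(ps24$patterns["7mer-A1"]), "TGAGCCA")
  expect_identical(unname(ps24$patterns["8mer"]), "CTGAGCCA")
  ps23 <- build_site_patterns("miR-23b", "AUCACAUUGCCAGGGAUUACC")
  expect_identical(ps23$seed6, "UCACAU")
  # miRNAs sharing nucleotides 2-8 yield identical pattern sets
  ps_same <- build_site_patterns("other", "AGGCUCAGAAAAAAAAAA")
  expect_identical(ps_same$patterns, ps24$patterns)
  expect_error(build_site_patterns("short", "ACGUACG"), "8 nt")
})

test_that("scanning applies longest-site precedence at a shared locus", {
  ps <- build_site_patterns("miR-24", "UGGCUCAGUUCAGCAGGAACAG")
  hits <- scan_utr("AAACTGAGCCAAAA", ps, gene_id = "g")
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$site_type, "8mer")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 11L)
  expect_identical(substr("AAACTGAGCCAAAA", hits$start + 1, hits$end), "CTGAGCCA")
  # without collapsing, the contained 7mers and 6mer are reported too
  all_hits <- scan_utr("AAACTGAGCCAAAA", ps, collapse = FALSE)
  expect_setequal(all_hits$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  # pattern absent -> empty result
  expect_equal(nrow(scan_utr("GGGGGGGG", ps)), 0L)
})

test_that("scanning equals a naive substring oracle on random sequences", {
  set.seed(62)
  ps <- build_site_patterns("miR-24", "UGGCUCAGUUCAGCAGGAACAG")
  seqs <- random_dna(300, 500)
  for (s in seqs[1:50]) {
    hits <- scan_utr(s, ps, collapse = FALSE)
    for (ty in c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
      expect_equal(hits$start[hits$site_type == ty],
                   naive_find(s, ps$patterns[[ty]]))
    }
  }
})

test_that("sites require the reverse complement of the seed on the UTR strand", {
  mat <- "UGGCUCAGUUCAGCAGGAACAG"
  ps <- build_site_patterns("miR-24", mat)
  seed7_rna <- substr(mat, 2, 8)
  rc_site <- reverse_complement(chartr("U", "T", seed7_rna))  # CTGAGCC
  bg <- paste(rep("A", 30), collapse = "")
  with_rc <- paste0(bg, rc_site, bg)
  with_seed <- paste0(bg, chartr("U", "T", seed7_rna), bg)  # GGCTCAG, not a site
  expect_true(any(scan_utr(with_rc, ps)$site_type %in% c("7mer-m8", "8mer")))
  expect_false(any(scan_utr(with_seed, ps)$site_type %in% c("7mer-m8", "8mer")))
})

test_that("chance 7mer site counts match the i.i.d. expectation", {
  set.seed(63)
  L <- 400
  n <- 1000
  seqs <- utr_set(random_dna(n, L))
  cat <- mirna_catalog("miR-24", "UGGCUCAGUUCAGCAGGAACAG")
  pred <- predict_targets(cat, seqs, min_site_type = "7mer-m8", collapse = FALSE)
  m8 <- pred$sites[pred$sites$site_type == "7mer-m8", ]
  n_positions <- n * (L - 6)
  expected <- n_positions * 4^-7
  sd3 <- 3 * sqrt(n_positions * 4^-7 * (1 - 4^-7))
  observed <- nrow(m8)
  expect_gt(observed, expected - sd3)
  expect_lt(observed, expected + sd3)
})

test_that("target prediction is monotone in the minimum site type", {
  set.seed(64)
  seqs <- utr_set(random_dna(200, 300))
  cat <- rbind(mir23b_cluster_catalog(),
               mirna_catalog("miR-sim", "ACGUACGUACGUACGUACGU"))
  class(cat) <- c("mirna_catalog", "data.frame")
  preds <- lapply(c("6mer", "7mer-A1", "7mer-m8", "8mer"), function(ty)
    predict_targets(cat, seqs, min_site_type = ty)$targets)
  for (k in 2:4) {
    for (m in cat$name) {
      expect_true(all(preds[[k]][[m]] %in% preds[[k - 1]][[m]]))
    }
  }
})

test_that("planted sites are recovered and weaker-only UTRs yield no strong calls", {
  cfg <- sim_config(n_mirnas = 5, n_genes = 60, n_true_targets_per_member = 4,
                    utr_length_range = c(100L, 200L), seed = 7L)
  gen <- generate_utr_set(cfg)
  pred <- predict_targets(mir23b_cluster_catalog(), gen$utrs,
                          min_site_type = "7mer-m8")
  for (m in names(gen$truth$target_map)) {
    expect_true(all(gen$truth$target_map[[m]] %in% pred$targets[[m]]))
  }
  # an 8mer-only threshold on 7mer-m8-planted UTRs finds at most chance hits
  pred8 <- predict_targets(mir23b_cluster_catalog(), gen$utrs,
                           min_site_type = "8mer")
  planted <- gen$truth$planted_sites
  for (i in seq_len(nrow(planted))) {
    sc <- scan_utr(gen$utrs[[planted$gene_id[i]]],
                   build_site_patterns(planted$mirna[i], mir23b_cluster_catalog()$mature_seq[
                     match(planted$mirna[i], mir23b_cluster_catalog()$name)]),
                   gene_id = planted$gene_id[i])
    hit <- sc[sc$start == planted$start[i], ]
    expect_gte(nrow(hit), 1L)
    expect_true(all(match(hit$site_type, c("6mer", "7mer-A1", "7mer-m8", "8mer")) >= 3))
  }
})
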