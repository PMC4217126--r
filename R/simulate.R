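#' Mature sequences of the miR-23b-24-27b genomic cluster
#'
#' The three co-located murine miRNAs used as the default planted cluster of
#' the synthetic generator: miR-23b (AUCACAUUGCCAGGGAUUACC), miR-24
#' (UGGCUCAGUUCAGCAGGAACAG) and miR-27b (UUCACAGUGGCUAAGUUCUGC).
#'
#' @return a [mirna_catalog()] with three rows sharing cluster id
#'   `"miR-23b-24-27b"`.
#' @export
mir23b_cluster_catalog <- function() {
  mirna_catalog(
    name = c("mmu-miR-23b", "mmu-miR-24", "mmu-miR-27b"),
    mature_seq = c("AUCACAUUGCCAGGGAUUACC",
                   "UGGCUCAGUUCAGCAGGAACAG",
                   "UUCACAGUGGCUAAGUUCUGC"),
    cluster_id = "miR-23b-24-27b")
}

# Deterministic sub-seed derivation from the master seed (documented splitting
# scheme; keeps every derived seed a valid 32-bit integer).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Configuration of the synthetic two-group microarray experiment
#'
#' Defines the truth-known simulation: a two-group design (default 5 vs 5
#' arrays) in which one 3-member genomic miRNA cluster is downregulated while
#' its planted seed-bearing mRNA targets are upregulated, under i.i.d.
#' Gaussian noise on the log2 scale (multiplicative log-normal intensities).
#' The planted cluster defaults to the miR-23b-24-27b mature sequences; the
#' remaining miRNAs are random 22-mers without a cluster.
#'
#' @param n_mirnas number of miRNAs on the simulated miRNA array.
#' @param n_genes number of genes (with 3'UTRs) on the simulated mRNA array.
#' @param n_per_group arrays per group (>= 2; default 5).
#' @param planted_catalog a [mirna_catalog()] providing the planted cluster
#'   members (all rows must share one non-NA cluster id).
#' @param mirna_effect_log2 log2 fold change applied to planted cluster
#'   members in the treated group (negative = downregulated).
#' @param n_true_targets_per_member planted target genes per cluster member
#'   (targets are disjoint across members).
#' @param target_effect_log2 log2 fold change applied to planted target genes
#'   (positive = upregulated).
#' @param utr_length_range min/max UTR length in nt.
#' @param background_gc GC fraction of background UTR sequence.
#' @param noise_sd_log2 per-observation Gaussian noise sd on the log2 scale.
#' @param site_type site type planted in target UTRs (default `"7mer-m8"`).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return list of class `sim_config`. The `rng` element records the RNG
#'   ("Mersenne-Twister") for reproducibility metadata.
#' @export
sim_config <- function(n_mirnas = 60L, n_genes = 600L, n_per_group = 5L,
                       planted_catalog = mir23b_cluster_catalog(),
                       mirna_effect_log2 = -1.5,
                       n_true_targets_per_member = 10L,
                       target_effect_log2 = 1.0,
                       utr_length_range = c(200L, 600L),
                       background_gc = 0.5,
                       noise_sd_log2 = 0.25,
                       site_type = "7mer-m8",
                       seed = 1L) {
  stopifnot(n_mirnas >= nrow(planted_catalog), n_genes > 0, n_per_group >= 2,
            noise_sd_log2 >= 0, background_gc > 0, background_gc < 1,
            utr_length_range[1L] >= 8L,
            utr_length_range[2L] >= utr_length_range[1L],
            site_type %in% SITE_TYPES)
  cl <- unique(planted_catalog$cluster_id)
  if (length(cl) != 1L || is.na(cl))
    stop("planted catalog rows must share one non-NA cluster id")
  if (nrow(planted_catalog) * n_true_targets_per_member > n_genes)
    stop("not enough genes to host the planted targets")
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    n_per_group = as.integer(n_per_group),
    planted_catalog = planted_catalog,
    planted_down_cluster = cl,
    mirna_effect_log2 = mirna_effect_log2,
    n_true_targets_per_member = as.integer(n_true_targets_per_member),
    target_effect_log2 = target_effect_log2,
    utr_length_range = as.integer(utr_length_range),
    background_gc = background_gc,
    noise_sd_log2 = noise_sd_log2,
    site_type = site_type,
    seed = as.integer(seed),
    rng = "Mersenne-Twister"), class = "sim_config")
}

# Deterministic experiment plan: gene ids, full miRNA catalog (planted members
# plus random 22-mers), and the planted target map (disjoint across members).
plan_truth <- function(config) {
  set.seed(derive_seed(config$seed, 11L), kind = "Mersenne-Twister")
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  n_extra <- config$n_mirnas - nrow(config$planted_catalog)
  extra <- if (n_extra > 0L) {
    mirna_catalog(
      name = sprintf("miR-sim-%03d", seq_len(n_extra)),
      mature_seq = vapply(seq_len(n_extra), function(i)
        paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = ""),
        character(1L)),
      cluster_id = NA_character_)
  } else NULL
  catalog <- rbind(config$planted_catalog, extra)
  class(catalog) <- c("mirna_catalog", "data.frame")
  members <- config$planted_catalog$name
  pool <- sample(gene_ids)
  target_map <- list()
  k <- 0L
  for (m in members) {
    target_map[[m]] <- sort(pool[(k + 1L):(k + config$n_true_targets_per_member)])
    k <- k + config$n_true_targets_per_member
  }
  list(gene_ids = gene_ids, catalog = catalog, members = members,
       target_map = target_map,
       de_mirnas = members,
       de_genes = sort(unlist(target_map, use.names = FALSE)))
}

#' Generate a synthetic 3'UTR set with planted seed-match sites
#'
#' Background sequence is i.i.d. at the configured GC fraction; for every
#' planted (miRNA, target gene) pair one site of the configured type is
#' written over the background at a uniformly random position (sites within a
#' gene never overlap; UTR length is preserved). The returned truth records
#' site positions (0-based) for cross-module checks.
#'
#' @param config a [sim_config()].
#' @return list with `utrs` (a [utr_set()]) and `truth` (list: `de_mirnas`,
#'   `de_genes`, `target_map`, `planted_sites` data frame with `gene_id`,
#'   `mirna`, `site_type`, `start`, `end`).
#' @export
generate_utr_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- plan_truth(config)
  set.seed(derive_seed(config$seed, 12L), kind = "Mersenne-Twister")
  gc <- config$background_gc
  len_choices <- seq(config$utr_length_range[1L], config$utr_length_range[2L])
  lens <- len_choices[sample.int(length(len_choices), config$n_genes,
                                 replace = TRUE)]
  base <- vapply(lens, function(L)
    paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = ""), character(1L))
  names(base) <- plan$gene_ids

  occupied <- lapply(base, function(x) integer(0L))
  site_rows <- list()
  for (m in plan$members) {
    ps <- build_site_patterns(m, plan$catalog$mature_seq[plan$catalog$name == m])
    pat <- ps$patterns[[config$site_type]]
    w <- nchar(pat)
    for (g in plan$target_map[[m]]) {
      L <- nchar(base[[g]])
      if (L < w) stop("UTR of ", g, " too short to host a ", config$site_type, " site")
      repeat {
        start <- sample.int(L - w + 1L, 1L) - 1L  # 0-based
        span <- (start + 1L):(start + w)
        if (!length(intersect(span, occupied[[g]]))) break
      }
      substr(base[[g]], start + 1L, start + w) <- pat
      occupied[[g]] <- c(occupied[[g]], span)
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(gene_id = g, mirna = m, site_type = config$site_type,
                   start = start, end = start + w, stringsAsFactors = FALSE)
    }
  }
  planted_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(0L), mirna = character(0L),
               site_type = character(0L), start = integer(0L),
               end = integer(0L), stringsAsFactors = FALSE)
  list(utrs = utr_set(base),
       truth = list(de_mirnas = plan$de_mirnas, de_genes = plan$de_genes,
                    target_map = plan$target_map,
                    planted_sites = planted_sites))
}

# Two-group log-normal intensity matrix on the log2 scale: per-feature
# baseline ~ Uniform(6, 12); treated-group means shifted by `effects`
# (named by feature); observation = mean + Normal(0, sd).
simulate_matrix <- function(feature_ids, n_per_group, effects, sd) {
  n <- length(feature_ids)
  baseline <- stats::runif(n, 6, 12)
  shift <- rep(0, n)
  shift[match(names(effects), feature_ids)] <- effects
  samples <- c(paste0("control_", seq_len(n_per_group)),
               paste0("treated_", seq_len(n_per_group)))
  mu <- cbind(matrix(baseline, n, n_per_group),
              matrix(baseline + shift, n, n_per_group))
  vals <- mu + matrix(stats::rnorm(n * 2L * n_per_group, sd = sd), n)
  dimnames(vals) <- list(feature_ids, samples)
  groups <- stats::setNames(rep(c("control", "treated"), each = n_per_group), samples)
  expression_matrix(vals, groups, log2_scale = TRUE,
                    group_levels = c("control", "treated"))
}

#' Generate a complete synthetic miRNA/mRNA microarray experiment
#'
#' Produces the paired miRNA and mRNA expression matrices (two groups,
#' `n_per_group` arrays each, log2 scale), the UTR set with planted sites,
#' the miRNA catalog, and the ground truth. Planted cluster members are
#' shifted by `mirna_effect_log2` and their planted target genes by
#' `target_effect_log2` in the treated group.
#'
#' @param config a [sim_config()].
#' @return list with `mirna`, `mrna` (both [expression_matrix()]), `utrs`,
#'   `catalog`, `truth`.
#' @export
generate_expression_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- plan_truth(config)
  utr <- generate_utr_set(config)
  set.seed(derive_seed(config$seed, 13L), kind = "Mersenne-Twister")
  mirna_effects <- stats::setNames(
    rep(config$mirna_effect_log2, length(plan$members)), plan$members)
  mirna <- simulate_matrix(plan$catalog$name, config$n_per_group,
                           mirna_effects, config$noise_sd_log2)
  gene_effects <- stats::setNames(
    rep(config$target_effect_log2, length(plan$de_genes)), plan$de_genes)
  mrna <- simulate_matrix(plan$gene_ids, config$n_per_group,
                          gene_effects, config$noise_sd_log2)
  list(mirna = mirna, mrna = mrna, utrs = utr$utrs, catalog = plan$catalog,
       truth = utr$truth)
}

#' Generate a synthetic qPCR Ct table with a planted effect
#'
#' Reference-gene Ct ~ Normal(20, sd); target Ct = reference Ct + baseline
#' dCt - planted effect (cycles, treated group only) + Normal(0, sd) noise,
#' so the expected delta-delta-Ct fold change of the treated group is
#' `2^effect_cycles`.
#'
#' @param effect_cycles planted treated-group decrease of the target's Ct in
#'   cycles (1 cycle = 2-fold).
#' @param n_per_group samples per group (>= 2).
#' @param sd Gaussian sd of both reference and target Ct, in cycles.
#' @param seed integer seed.
#' @param baseline_dct baseline target-minus-reference Ct difference.
#' @return a [ct_table()] with genes `"target"` and reference `"ref"`,
#'   groups `"control"` (the control group) and `"treated"`.
#' @export
generate_ct_table <- function(effect_cycles = 1, n_per_group = 6L, sd = 0.2,
                              seed = 1L, baseline_dct = 5) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  set.seed(derive_seed(seed, 14L), kind = "Mersenne-Twister")
  samples <- c(paste0("control_", seq_len(n_per_group)),
               paste0("treated_", seq_len(n_per_group)))
  group <- rep(c("control", "treated"), each = n_per_group)
  ref_ct <- stats::rnorm(2L * n_per_group, mean = 20, sd = sd)
  eff <- ifelse(group == "treated", effect_cycles, 0)
  target_ct <- ref_ct + baseline_dct - eff +
    stats::rnorm(2L * n_per_group, mean = 0, sd = sd)
  ct_table(data.frame(
    sample_id = rep(samples, 2L), group = rep(group, 2L),
    gene = rep(c("ref", "target"), each = 2L * n_per_group),
    ct = c(ref_ct, target_ct), stringsAsFactors = FALSE),
    reference_gene = "ref", control_group = "control")
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits the files a file-based pipeline run consumes: `utrs.fasta`,
#' `mirna_matrix.tsv`, `mrna_matrix.tsv`, `groups.tsv`, `catalog.tsv`, and
#' the ground truth (`truth_targets.tsv`, `truth_sites.tsv`).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the [generate_expression_experiment()] result.
#' @export
simulate_bundle <- function(config, dir) {
  ex <- generate_expression_experiment(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_utrs(ex$utrs, file.path(dir, "utrs.fasta"))
  write_expression_matrix(ex$mirna, file.path(dir, "mirna_matrix.tsv"),
                          file.path(dir, "groups.tsv"))
  write_expression_matrix(ex$mrna, file.path(dir, "mrna_matrix.tsv"))
  write_report(as.data.frame(ex$catalog), file.path(dir, "catalog.tsv"))
  tm <- ex$truth$target_map
  write_report(data.frame(
    mirna = rep(names(tm), lengths(tm)),
    gene_id = unlist(tm, use.names = FALSE), stringsAsFactors = FALSE),
    file.path(dir, "truth_targets.tsv"))
  write_report(ex$truth$planted_sites, file.path(dir, "truth_sites.tsv"))
  invisible(ex)
}
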