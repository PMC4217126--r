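#' Configuration of the end-to-end discovery pipeline
#'
#' Collects the test choices and thresholds of the integrative analysis:
#' miRNA DE by moderated t (BH q reported; calls gated on raw p by default)
#' at >1.5-fold and p <= 0.05, an additional Wilcoxon p <= 0.05 miRNA list
#' feeding the hexamer enrichment, and mRNA DE by two-class unpaired SAM at
#' estimated FDR <= 0.01.
#'
#' @param mirna_fc_min minimum linear fold change for miRNA calls.
#' @param mirna_p_max significance cutoff for miRNA calls.
#' @param mirna_use_q gate miRNA calls on BH q instead of raw p.
#' @param mrna_fdr target median FDR for SAM mRNA calls.
#' @param sam_n_perm random permutations when enumeration is infeasible.
#' @param sam_s0_grid optional explicit s0 grid passed to [sam_two_class()]
#'   (needed for noise-free data where every feature has zero scatter).
#' @param min_site_type weakest site type counting as a predicted target.
#' @param hexamer_per_kb length-normalize hexamer counts.
#' @param cluster_mode cluster aggregation, `"union"` or `"sum"`.
#' @param seed master seed for the permutation stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fc_min = 1.5, mirna_p_max = 0.05,
                            mirna_use_q = FALSE, mrna_fdr = 0.01,
                            sam_n_perm = 1000L, sam_s0_grid = NULL,
                            min_site_type = "7mer-m8",
                            hexamer_per_kb = FALSE,
                            cluster_mode = "union", seed = 1L) {
  stopifnot(mirna_fc_min > 1, mirna_p_max > 0, mirna_p_max <= 1,
            mrna_fdr > 0, mrna_fdr <= 1, min_site_type %in% SITE_TYPES)
  structure(list(mirna_fc_min = mirna_fc_min, mirna_p_max = mirna_p_max,
                 mirna_use_q = mirna_use_q, mrna_fdr = mrna_fdr,
                 sam_n_perm = as.integer(sam_n_perm),
                 sam_s0_grid = sam_s0_grid,
                 min_site_type = min_site_type,
                 hexamer_per_kb = hexamer_per_kb,
                 cluster_mode = cluster_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the integrative miRNA-mRNA discovery analysis end to end
#'
#' Stages: (1) miRNA DE by moderated t with BH correction, thresholded at
#' the configured fold change and significance level, plus a Wilcoxon
#' rank-sum DE miRNA list; (2) mRNA DE by two-class unpaired SAM at the
#' target FDR; (3) seed-match target prediction over the UTR set; (4)
#' per-miRNA and per-cluster anticorrelated-target counting and ranking; (5)
#' seed-hexamer enrichment of the upregulated versus non-regulated gene
#' lists over the Wilcoxon DE miRNAs. All randomness derives from the config
#' seed. With `out_dir` set, every stage table is also written as TSV along
#' with a run manifest.
#'
#' @param mirna,mrna [expression_matrix()] objects for the same two-group
#'   contrast (identical group labels).
#' @param utrs a [utr_set()] covering the mRNA features.
#' @param catalog a [mirna_catalog()] covering the miRNA features.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV reports.
#' @return list of class `pipeline_result` with elements `mirna_de`,
#'   `mirna_wilcoxon`, `sam`, `predictions`, `per_mirna`, `per_cluster`,
#'   `enrichment`, `config`.
#' @export
run_pipeline <- function(mirna, mrna, utrs, catalog,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mirna_de <- stage("mirna_de", threshold_de(
    moderated_t(mirna), fc_min = config$mirna_fc_min,
    p_max = config$mirna_p_max, use_q = config$mirna_use_q))
  mirna_wx <- stage("mirna_wilcoxon", wilcoxon_de(mirna))

  sam <- stage("mrna_sam", sam_two_class(
    mrna, n_perm = config$sam_n_perm, target_fdr = config$mrna_fdr,
    seed = derive_seed(config$seed, 21L), s0_grid = config$sam_s0_grid))
  mrna_up <- sam$up
  mrna_down <- sam$down

  pred <- stage("predict_targets", predict_targets(
    catalog, utrs, min_site_type = config$min_site_type))

  per_mirna <- stage("anticorrelated_targets", anticorrelated_targets(
    mirna_de, mrna_up, mrna_down, pred$targets,
    mrna_universe = rownames(mrna$values)))
  cluster_of <- stats::setNames(catalog$cluster_id, catalog$name)
  per_cluster <- stage("rank_clusters", rank_clusters(
    per_mirna, cluster_of, mode = config$cluster_mode))

  # hexamer stage uses the Wilcoxon p<=0.05 DE miRNA list and contrasts the
  # SAM-upregulated genes against the non-regulated remainder
  wx_de <- mirna_wx$feature_id[mirna_wx$p <= 0.05]
  ns_genes <- setdiff(rownames(mrna$values), union(mrna_up, mrna_down))
  enrichment <- NULL
  if (length(wx_de) && length(mrna_up) && length(ns_genes)) {
    de_cat <- catalog[catalog$name %in% wx_de, , drop = FALSE]
    class(de_cat) <- c("mirna_catalog", "data.frame")
    if (nrow(de_cat))
      enrichment <- stage("hexamer_enrichment", mirextra_enrichment(
        intersect(mrna_up, names(utrs)), intersect(ns_genes, names(utrs)),
        utrs, de_cat, per_kb = config$hexamer_per_kb))
  }

  res <- structure(list(mirna_de = mirna_de, mirna_wilcoxon = mirna_wx,
                        sam = sam, predictions = pred,
                        per_mirna = per_mirna, per_cluster = per_cluster,
                        enrichment = enrichment, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

# TSV report bundle plus a manifest sufficient to re-run the analysis.
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(res$mirna_de, file.path(out_dir, "mirna_de.tsv"))
  write_report(res$mirna_wilcoxon, file.path(out_dir, "mirna_wilcoxon.tsv"))
  write_report(res$sam$table, file.path(out_dir, "mrna_sam.tsv"))
  write_report(res$predictions$sites, file.path(out_dir, "predicted_sites.tsv"))
  write_report(res$per_mirna, file.path(out_dir, "anticorr_per_mirna.tsv"))
  write_report(res$per_cluster, file.path(out_dir, "anticorr_per_cluster.tsv"))
  if (!is.null(res$enrichment))
    write_report(res$enrichment, file.path(out_dir, "hexamer_enrichment.tsv"))
  cfg <- res$config
  manifest <- data.frame(
    key = c("package_version", "seed", "mirna_fc_min", "mirna_p_max",
            "mirna_use_q", "mrna_fdr", "sam_n_perm", "min_site_type",
            "hexamer_per_kb", "cluster_mode", "sam_s0", "sam_delta",
            "sam_estimated_fdr"),
    value = c(as.character(utils::packageVersion("mircross")),
              cfg$seed, cfg$mirna_fc_min, cfg$mirna_p_max, cfg$mirna_use_q,
              cfg$mrna_fdr, cfg$sam_n_perm, cfg$min_site_type,
              cfg$hexamer_per_kb, cfg$cluster_mode,
              sprintf("%.10g", res$sam$s0), sprintf("%.10g", res$sam$delta),
              sprintf("%.10g", res$sam$estimated_fdr)),
    stringsAsFactors = FALSE)
  write_report(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(NULL)
}
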