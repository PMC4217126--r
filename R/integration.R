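#' Count anticorrelated predicted targets per differentially expressed miRNA
#'
#' For every significantly regulated miRNA, intersect its predicted target
#' genes with the mRNAs regulated in the opposite direction in the same
#' contrast: a DOWN miRNA is matched against UP mRNAs and vice versa.
#' Non-significant miRNAs are excluded. Predicted gene ids absent from the
#' mRNA universe are ignored (with a message).
#'
#' @param mirna_calls a `de_table` with a `call` column (see
#'   [threshold_de()]) for the miRNA contrast.
#' @param mrna_up,mrna_down character vectors of up- and downregulated mRNA
#'   ids from the same contrast.
#' @param predictions named list miRNA -> predicted gene ids (see
#'   [predict_targets()]).
#' @param mrna_universe all mRNA ids measured; defaults to
#'   `union(mrna_up, mrna_down)` plus every predicted id (i.e. no filtering)
#'   unless given.
#' @return data frame of class `anticorr_table`: `mirna`, `direction`,
#'   `n_anticorr`, `mean_abs_lfc`, `anticorr_genes` (comma-separated), plus
#'   attribute `gene_sets` (named list of the underlying sets).
#' @export
anticorrelated_targets <- function(mirna_calls, mrna_up, mrna_down,
                                   predictions, mrna_universe = NULL) {
  stopifnot(all(c("feature_id", "call", "log2_fc") %in% names(mirna_calls)))
  de <- mirna_calls[mirna_calls$call != "ns", , drop = FALSE]
  if (!is.null(mrna_universe)) {
    orphan <- setdiff(unique(unlist(predictions)), mrna_universe)
    if (length(orphan))
      message(length(orphan), " predicted gene id(s) absent from the mRNA universe; ignored")
    predictions <- lapply(predictions, intersect, mrna_universe)
  }
  sets <- list()
  rows <- lapply(seq_len(nrow(de)), function(i) {
    m <- de$feature_id[i]
    dir <- as.character(de$call[i])
    pred <- predictions[[m]]
    anti <- if (identical(dir, "down")) intersect(pred, mrna_up)
            else intersect(pred, mrna_down)
    sets[[m]] <<- sort(anti)
    data.frame(mirna = m, direction = dir, n_anticorr = length(anti),
               mean_abs_lfc = abs(de$log2_fc[i]),
               anticorr_genes = paste(sort(anti), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0L), direction = character(0L),
               n_anticorr = integer(0L), mean_abs_lfc = numeric(0L),
               anticorr_genes = character(0L), stringsAsFactors = FALSE)
  out <- out[order(-out$n_anticorr, -out$mean_abs_lfc, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anticorr_table", "data.frame")
  attr(out, "gene_sets") <- sets
  out
}

#' Aggregate anticorrelated-target counts to genomic miRNA clusters and rank
#'
#' Each cluster's anticorrelated set is the union of its significant members'
#' sets (distinct genes); miRNAs without a cluster id form singleton
#' pseudo-clusters and rank alongside true clusters. Entities are ranked by
#' descending distinct-gene count, ties broken by descending mean |miRNA
#' log2 fold change| over members, then lexicographic id. `mode = "sum"`
#' replaces the union count with the sum of member counts (sensitivity
#' analysis only).
#'
#' @param per_mirna an `anticorr_table` from [anticorrelated_targets()].
#' @param cluster_of named character vector miRNA -> cluster id (`NA` or
#'   missing entries become singleton pseudo-clusters named after the miRNA).
#' @param mode `"union"` (default) or `"sum"`.
#' @return data frame of class `anticorr_table`: `cluster_id`, `members`,
#'   `direction`, `n_anticorr`, `mean_abs_lfc`, `rank`, `anticorr_genes`,
#'   with attribute `gene_sets`.
#' @export
rank_clusters <- function(per_mirna, cluster_of, mode = c("union", "sum")) {
  mode <- match.arg(mode)
  if (nrow(per_mirna) == 0L) {
    out <- data.frame(cluster_id = character(0L), members = character(0L),
                      direction = character(0L), n_anticorr = integer(0L),
                      mean_abs_lfc = numeric(0L), anticorr_genes = character(0L),
                      rank = integer(0L), stringsAsFactors = FALSE)
    class(out) <- c("anticorr_table", "data.frame")
    attr(out, "gene_sets") <- list()
    return(out)
  }
  sets <- attr(per_mirna, "gene_sets")
  cl <- cluster_of[per_mirna$mirna]
  cl[is.na(cl)] <- per_mirna$mirna[is.na(cl)]
  groups <- split(seq_len(nrow(per_mirna)), cl)
  rows <- lapply(names(groups), function(cid) {
    ii <- groups[[cid]]
    gset <- sort(unique(unlist(sets[per_mirna$mirna[ii]])))
    n <- if (mode == "union") length(gset) else sum(per_mirna$n_anticorr[ii])
    dirs <- unique(per_mirna$direction[ii])
    data.frame(cluster_id = cid,
               members = paste(sort(per_mirna$mirna[ii]), collapse = ","),
               direction = paste(sort(dirs), collapse = "/"),
               n_anticorr = n,
               mean_abs_lfc = mean(per_mirna$mean_abs_lfc[ii]),
               anticorr_genes = paste(gset, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_anticorr, -out$mean_abs_lfc, out$cluster_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("anticorr_table", "data.frame")
  attr(out, "gene_sets") <- lapply(names(groups), function(cid)
    sort(unique(unlist(sets[per_mirna$mirna[groups[[cid]]]]))))
  names(attr(out, "gene_sets")) <- names(groups)
  out
}
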