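#' Construct a qPCR Ct table
#'
#' Long-format quantification-cycle (Ct) measurements: one row per
#' (sample, gene), with the sample's group label. A reference gene (the
#' multiplexed internal control, e.g. 18S or sno202) must be measured in
#' every sample that carries a target-gene measurement, and a control group
#' anchors the delta-delta-Ct comparison.
#'
#' @param data data frame with columns `sample_id`, `group`, `gene`, `ct`.
#' @param reference_gene name of the normalization gene.
#' @param control_group group label of the untreated/control arm.
#' @return data frame of class `ct_table` with attributes `reference_gene`
#'   and `control_group`.
#' @export
ct_table <- function(data, reference_gene, control_group) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(data)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  data <- data[need]
  data$ct <- as.numeric(data$ct)
  if (any(!is.finite(data$ct)) || any(data$ct <= 0))
    stop("Ct values must be finite and positive")
  if (anyDuplicated(data[c("sample_id", "gene")]))
    stop("duplicate (sample_id, gene) measurement")
  if (!reference_gene %in% data$gene)
    stop("reference gene '", reference_gene, "' not measured")
  if (!control_group %in% data$group)
    stop("control group '", control_group, "' has no samples")
  ref_samples <- data$sample_id[data$gene == reference_gene]
  missing_ref <- setdiff(unique(data$sample_id), ref_samples)
  if (length(missing_ref))
    stop("reference gene missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  structure(data, class = c("ct_table", "data.frame"),
            reference_gene = reference_gene, control_group = control_group)
}

#' Read a Ct table from TSV
#'
#' @param path tab-delimited file with header `sample_id, group, gene, ct`.
#' @param reference_gene,control_group see [ct_table()].
#' @return a `ct_table`.
#' @export
read_ct_table <- function(path, reference_gene, control_group) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ct_table(tab, reference_gene, control_group)
}
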