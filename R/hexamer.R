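#' Count occurrences of a seed hexamer per UTR
#'
#' Overlapping occurrences of the exact 6-nt word in each UTR, optionally
#' normalized per kilobase of UTR length.
#'
#' @param utrs a [utr_set()].
#' @param hexamer 6-nt string in the DNA alphabet (U spellings accepted).
#' @param per_kb if `TRUE`, divide each count by `nchar(utr)/1000`.
#' @return named numeric vector, one entry per gene.
#' @export
hexamer_counts <- function(utrs, hexamer, per_kb = FALSE) {
  stopifnot(inherits(utrs, "utr_set"))
  hexamer <- normalize_dna(hexamer, what = "hexamer")
  if (nchar(hexamer) != 6L) stop("hexamer must be exactly 6 nt")
  subject <- Biostrings::DNAStringSet(unclass(utrs))
  cnt <- Biostrings::vcountPattern(hexamer, subject, fixed = TRUE)
  names(cnt) <- names(utrs)
  if (per_kb) cnt <- cnt / (nchar(unclass(utrs)) / 1000)
  cnt
}

#' Rank differentially expressed miRNAs by seed-hexamer enrichment
#'
#' For each miRNA the single seed hexamer (reverse complement of mature
#' nucleotides 2-7, target strand) is counted in the 3'UTRs of the regulated
#' gene list and of the non-regulated background list, and the two count
#' vectors are compared with a one-sided Wilcoxon rank-sum test (alternative:
#' counts in the regulated list are stochastically greater). Because counts
#' are heavily tied, the normal approximation with mid-rank tie correction
#' (no continuity correction) is used beyond small samples. miRNAs are ranked by descending `-ln(p)`.
#'
#' @param up_genes character vector of regulated gene ids (disjoint from
#'   `background_genes`).
#' @param background_genes character vector of non-regulated gene ids.
#' @param utrs a [utr_set()]; genes missing a UTR are dropped with a message.
#' @param de_mirnas a [mirna_catalog()] restricted to the differentially
#'   expressed miRNAs to rank.
#' @param per_kb normalize counts per kilobase before testing.
#' @return data frame of class `enrichment_table` with columns `mirna`,
#'   `hexamer`, `W`, `p`, `neg_ln_p`, `rank`, sorted by descending
#'   `neg_ln_p`.
#' @export
mirextra_enrichment <- function(up_genes, background_genes, utrs, de_mirnas,
                                per_kb = FALSE) {
  stopifnot(inherits(utrs, "utr_set"))
  if (length(intersect(up_genes, background_genes)))
    stop("regulated and background gene lists must be disjoint")
  drop_up <- setdiff(up_genes, names(utrs))
  drop_bg <- setdiff(background_genes, names(utrs))
  if (length(drop_up) || length(drop_bg))
    message("dropping ", length(drop_up) + length(drop_bg),
            " gene(s) without a UTR")
  up_genes <- intersect(up_genes, names(utrs))
  background_genes <- intersect(background_genes, names(utrs))
  if (!length(up_genes) || !length(background_genes))
    stop("both gene lists must be non-empty and present in the UTR set")
  if (nrow(de_mirnas) == 0L) stop("no miRNAs to rank")

  sub <- utr_set(unclass(utrs)[c(up_genes, background_genes)])
  n_up <- length(up_genes)
  rows <- lapply(seq_len(nrow(de_mirnas)), function(i) {
    ps <- build_site_patterns(de_mirnas$name[i], de_mirnas$mature_seq[i])
    cnt <- hexamer_counts(sub, ps$patterns[["6mer"]], per_kb = per_kb)
    x_up <- cnt[seq_len(n_up)]
    x_bg <- cnt[-seq_len(n_up)]
    r <- rank(c(x_up, x_bg))
    w <- sum(r[seq_len(n_up)]) - n_up * (n_up + 1L) / 2
    ties <- table(c(x_up, x_bg))
    exact <- (n_up + length(x_bg)) <= 12L && all(ties == 1L)
    p <- rank_sum_p(w, length(x_bg), n_up, as.numeric(ties), exact,
                    alternative = "greater", continuity = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    data.frame(mirna = de_mirnas$name[i], hexamer = ps$patterns[["6mer"]],
               W = w, p = p, neg_ln_p = -log(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$neg_ln_p, out$mirna), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Bar chart of hexamer enrichment, ranked by -ln(p)
#'
#' @param enrichment an `enrichment_table` from [mirextra_enrichment()].
#' @param top number of top-ranked miRNAs to show.
#' @param highlight optional character vector of miRNA names drawn in a
#'   darker shade (e.g. members of a cluster of interest).
#' @export
plot_enrichment <- function(enrichment, top = 20L, highlight = NULL) {
  e <- utils::head(enrichment, top)
  cols <- ifelse(e$mirna %in% highlight, "grey20", "grey70")
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(e$neg_ln_p, names.arg = e$mirna, las = 2, col = cols,
                    ylab = expression(-ln(italic(P))),
                    main = "Seed-hexamer enrichment in regulated 3'UTRs")
  invisible(e)
}
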