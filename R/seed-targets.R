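# Ordering of canonical seed-match site types, weakest first.
SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Derive seed-match site patterns from a mature miRNA sequence
#'
#' Canonical site types on the target (UTR sense) strand, 5'->3', in the DNA
#' alphabet, from miRNA 5'-end positions (1-based):
#' * `6mer` — reverse complement of nucleotides 2-7 (the seed);
#' * `7mer-m8` — reverse complement of nucleotides 2-8;
#' * `7mer-A1` — 6mer followed by `A`;
#' * `8mer` — 7mer-m8 followed by `A`.
#' The position-1 `A` is an anchor adenosine matched literally in the UTR,
#' not a complementarity requirement.
#'
#' @param name miRNA name.
#' @param mature_seq mature sequence (RNA or DNA spelling), length >= 8.
#' @return list of class `site_patterns` with `mirna`, `seed6` (RNA spelling
#'   of nucleotides 2-7) and `patterns` (named character vector over the four
#'   site types).
#' @export
build_site_patterns <- function(name, mature_seq) {
  seq_rna <- normalize_rna(mature_seq, what = "mature miRNA sequence")
  if (nchar(seq_rna) < 8L)
    stop("mature sequence must be at least 8 nt to define seed sites")
  seed6 <- substr(seq_rna, 2L, 7L)
  seed7 <- substr(seq_rna, 2L, 8L)
  p6 <- reverse_complement(normalize_dna(seed6), mode = "dna")
  p7m8 <- reverse_complement(normalize_dna(seed7), mode = "dna")
  structure(list(
    mirna = name,
    seed6 = seed6,
    patterns = c("6mer" = p6,
                 "7mer-A1" = paste0(p6, "A"),
                 "7mer-m8" = p7m8,
                 "8mer" = paste0(p7m8, "A"))),
    class = "site_patterns")
}

# site_patterns for every catalog row.
catalog_site_patterns <- function(catalog) {
  stopifnot(inherits(catalog, "mirna_catalog"))
  lapply(seq_len(nrow(catalog)), function(i)
    build_site_patterns(catalog$name[i], catalog$mature_seq[i]))
}

#' Scan one UTR for seed-match sites of one miRNA
#'
#' Finds all exact occurrences (overlapping included) of each site-type
#' pattern in the UTR. With `collapse = TRUE` (default) a longer site absorbs
#' shorter site types contained within its interval (8mer > 7mer-m8 /
#' 7mer-A1 > 6mer), so each locus is reported once at its strongest type.
#' Coordinates are 0-based, half-open, on the UTR sense strand.
#'
#' @param utr a single nucleotide string (internal DNA alphabet) or one
#'   element of a [utr_set()].
#' @param patterns a [build_site_patterns()] result.
#' @param gene_id id recorded in the output rows.
#' @param collapse drop shorter sites contained in a longer site.
#' @return data frame with columns `gene_id`, `mirna`, `site_type`, `start`,
#'   `end`, ordered by (`start`, descending site strength).
#' @export
scan_utr <- function(utr, patterns, gene_id = NA_character_, collapse = TRUE) {
  stopifnot(inherits(patterns, "site_patterns"))
  utr <- normalize_dna(as.character(utr), what = "UTR sequence")
  hits <- lapply(SITE_TYPES, function(ty) {
    pat <- patterns$patterns[[ty]]
    m <- gregexpr(pat, utr, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(gene_id = gene_id, mirna = patterns$mirna, site_type = ty,
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + nchar(pat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(gene_id = character(0L), mirna = character(0L),
                      site_type = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE))
  rk <- match(out$site_type, SITE_TYPES)
  if (collapse && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      contained <- out$start >= out$start[i] & out$end <= out$end[i] &
        rk < rk[i]
      keep[contained] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rk <- rk[keep]
  }
  out <- out[order(out$start, -rk), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict seed-match targets for a miRNA catalog across a UTR set
#'
#' A gene is a predicted target of a miRNA if its 3'UTR carries at least one
#' site whose type is at least `min_site_type` under the ordering
#' 6mer < 7mer-A1 < 7mer-m8 < 8mer.
#'
#' @param catalog a [mirna_catalog()].
#' @param utrs a [utr_set()].
#' @param min_site_type weakest site type that counts as a prediction
#'   (default `"7mer-m8"`).
#' @param collapse see [scan_utr()].
#' @return list with `targets` (named list: miRNA name -> character vector of
#'   predicted gene ids) and `sites` (data frame of all qualifying sites).
#' @export
predict_targets <- function(catalog, utrs, min_site_type = "7mer-m8",
                            collapse = TRUE) {
  stopifnot(inherits(utrs, "utr_set"), nrow(catalog) > 0L, length(utrs) > 0L)
  min_rank <- match(min_site_type, SITE_TYPES)
  if (is.na(min_rank)) stop("unknown site type: ", min_site_type)
  genes <- names(utrs)
  has_n <- grepl("N", unclass(utrs), fixed = TRUE)
  # N positions are masked before the exact vectorized scan; any gene
  # containing N is rescanned literally afterwards
  subject <- Biostrings::DNAStringSet(chartr("N", "A", unclass(utrs)))
  names(subject) <- genes
  pat_sets <- catalog_site_patterns(catalog)
  use_types <- SITE_TYPES[seq(min_rank, length(SITE_TYPES))]

  targets <- list()
  site_rows <- list()
  for (ps in pat_sets) {
    hits <- lapply(use_types, function(ty) {
      m <- Biostrings::vmatchPattern(ps$patterns[[ty]], subject)
      ir <- unlist(m)
      if (!length(ir)) return(NULL)
      data.frame(gene_id = names(ir), mirna = ps$mirna, site_type = ty,
                 start = BiocGenerics::start(ir) - 1L,
                 end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
    })
    sc <- do.call(rbind, hits)
    if (any(has_n)) {
      if (!is.null(sc)) sc <- sc[!has_n[sc$gene_id], , drop = FALSE]
      rescanned <- lapply(genes[has_n], function(g) {
        r <- scan_utr(utrs[[g]], ps, gene_id = g, collapse = FALSE)
        r[match(r$site_type, SITE_TYPES) >= min_rank, , drop = FALSE]
      })
      sc <- do.call(rbind, c(list(sc), rescanned))
      if (!is.null(sc) && !nrow(sc)) sc <- NULL
    }
    if (is.null(sc)) {
      targets[[ps$mirna]] <- character(0L)
      next
    }
    targets[[ps$mirna]] <- sort(unique(sc$gene_id))
    if (collapse && nrow(sc) > 1L) {
      rk <- match(sc$site_type, SITE_TYPES)
      parts <- split(seq_len(nrow(sc)), sc$gene_id)
      drop <- logical(nrow(sc))
      for (ii in parts) {
        if (length(ii) < 2L) next
        for (i in ii) for (j in ii) {
          if (rk[j] < rk[i] && sc$start[j] >= sc$start[i] && sc$end[j] <= sc$end[i])
            drop[j] <- TRUE
        }
      }
      sc <- sc[!drop, , drop = FALSE]
    }
    rk <- match(sc$site_type, SITE_TYPES)
    sc <- sc[order(sc$gene_id, sc$start, -rk), , drop = FALSE]
    site_rows[[ps$mirna]] <- sc
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(0L), mirna = character(0L),
               site_type = character(0L), start = integer(0L),
               end = integer(0L), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(targets = targets, sites = sites)
}
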