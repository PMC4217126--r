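#' Reverse complement of a nucleotide sequence
#'
#' Reverses the sequence and complements each base. The output alphabet
#' follows `mode`: DNA (`A/C/G/T`) or RNA (`A/C/G/U`); `N` maps to `N`. With
#' `mode = "auto"` the spelling of the input decides (any `U` implies RNA,
#' otherwise DNA).
#'
#' @param seq character vector of sequences over `A,C,G,T,U,N` (case
#'   insensitive; `T` and `U` may not be mixed meaningfully but both are
#'   accepted).
#' @param mode `"auto"`, `"dna"` or `"rna"`.
#' @return character vector of reverse complements, upper case.
#' @export
reverse_complement <- function(seq, mode = c("auto", "dna", "rna")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  bad <- grepl("[^ACGTUN]", seq)
  if (any(bad))
    stop("invalid character in sequence: ", seq[bad][1L])
  vapply(seq, function(s) {
    m <- if (mode == "auto") { if (grepl("U", s)) "rna" else "dna" } else mode
    comp <- if (m == "rna") chartr("ACGTUN", "UGCAAN", s) else chartr("ACGTUN", "TGCAAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Normalize a nucleotide string to the internal DNA alphabet (A,C,G,T,N):
# upper case, U -> T. Errors on anything else.
normalize_dna <- function(seq, what = "sequence") {
  seq <- chartr("U", "T", toupper(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("invalid character in ", what, ": ",
         gsub("[ACGTN]", "", seq[bad][1L]))
  seq
}

# Normalize to the RNA alphabet used for mature miRNA sequences (T -> U).
normalize_rna <- function(seq, what = "sequence") {
  seq <- chartr("T", "U", toupper(seq))
  bad <- grepl("[^ACGUN]", seq)
  if (any(bad))
    stop("invalid character in ", what, ": ",
         gsub("[ACGUN]", "", seq[bad][1L]))
  seq
}

#' Construct a named 3'UTR sequence set
#'
#' Sequences are stored internally in the DNA alphabet (`A,C,G,T,N`,
#' sense strand of the mRNA, 5'->3'); `U` spellings are normalized to `T`
#' on input so that mixed spellings scan identically.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return character vector of class `utr_set`.
#' @export
utr_set <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("UTR sequences must be named by gene id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene id: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty UTR sequence for gene: ",
                               names(seqs)[!nzchar(seqs)][1L])
  out <- vapply(seqs, normalize_dna, character(1L), what = "UTR sequence")
  structure(out, class = "utr_set")
}

#' Read 3'UTR sequences from a FASTA file
#'
#' Record ids are the token before the first whitespace in each header.
#' Sequences are upper-cased and normalized to the DNA alphabet (U -> T);
#' `N` is allowed.
#'
#' @param path FASTA file.
#' @return a [utr_set()].
#' @export
read_fasta_utrs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  utr_set(stats::setNames(as.character(ss), ids))
}

#' Write a UTR set as FASTA
#' @param utrs a `utr_set`.
#' @param path output file.
#' @export
write_fasta_utrs <- function(utrs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(utrs)), path, width = 70L)
  invisible(NULL)
}

#' Construct a miRNA catalog
#'
#' A catalog row holds a mature miRNA name, its mature sequence (RNA
#' alphabet, 5'->3'; `T` spellings normalized to `U`) and an optional genomic
#' cluster id grouping co-located miRNAs (e.g. the miR-23b-24-27b cluster).
#' miRNAs without a cluster are treated downstream as singleton
#' pseudo-clusters.
#'
#' @param name character vector of unique miRNA names.
#' @param mature_seq mature sequences, length >= 8.
#' @param cluster_id cluster labels; `NA` for unclustered miRNAs.
#' @return data frame of class `mirna_catalog` with columns
#'   `name`, `mature_seq`, `cluster_id`.
#' @export
mirna_catalog <- function(name, mature_seq, cluster_id = NA_character_) {
  if (anyDuplicated(name))
    stop("duplicate miRNA name: ", paste(unique(name[duplicated(name)]), collapse = ", "))
  mature_seq <- vapply(mature_seq, normalize_rna, character(1L),
                       what = "mature miRNA sequence", USE.NAMES = FALSE)
  short <- nchar(mature_seq) < 8L
  if (any(short))
    stop("mature sequence shorter than 8 nt for: ",
         paste(name[short], collapse = ", "))
  out <- data.frame(name = as.character(name),
                    mature_seq = mature_seq,
                    cluster_id = rep_len(as.character(cluster_id), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' Read a miRNA catalog from TSV
#'
#' @param path tab-delimited file with header and columns
#'   `name`, `mature_seq`, `cluster_id` (empty or `NA` cluster allowed).
#' @return a [mirna_catalog()].
#' @export
read_mirna_catalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "mature_seq", "cluster_id")
  if (!all(need %in% names(tab)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  cl <- tab$cluster_id
  cl[!nzchar(cl) | cl == "NA"] <- NA_character_
  mirna_catalog(tab$name, tab$mature_seq, cl)
}
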