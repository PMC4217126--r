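#' Construct an expression matrix with sample group labels
#'
#' The basic substrate of all differential-expression operations: a numeric
#' features x samples matrix with unique row and column names, a two-group (or
#' more) sample annotation, and an explicit flag recording whether values are
#' on the log2 scale. All DE math in this package is performed on log2
#' intensities; linear-scale input is transformed as `log2(x + offset)`.
#'
#' @param values numeric matrix, features in rows, samples in columns. Must
#'   carry unique, non-missing dimnames.
#' @param groups named character vector (or factor) mapping every sample id to
#'   its group label.
#' @param log2_scale logical; `TRUE` if `values` are already log2 intensities.
#'   If `FALSE` they are transformed with `log2(values + log2_offset)`.
#' @param log2_offset positive offset added before the log2 transform of
#'   linear-scale data. Ignored when `log2_scale = TRUE`.
#' @param group_levels optional character vector of length two (or more) fixing
#'   the order of group levels; the first level is the reference group so that
#'   fold changes read group2 vs group1. Defaults to sorted unique labels.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (log2 matrix), `groups` (factor named by sample id) and
#'   `log2_scale` (always `TRUE` after construction).
#' @export
expression_matrix <- function(values, groups, log2_scale = TRUE,
                              log2_offset = 1, group_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite; missing values are not supported")
  groups <- stats::setNames(as.character(groups), names(groups))
  missing_samples <- setdiff(colnames(values), names(groups))
  if (length(missing_samples))
    stop("samples missing a group label: ", paste(missing_samples, collapse = ", "))
  groups <- groups[colnames(values)]
  if (is.null(group_levels)) group_levels <- sort(unique(groups))
  if (!setequal(group_levels, unique(groups)))
    stop("'group_levels' must name exactly the observed group labels")
  if (!log2_scale) {
    if (log2_offset <= 0) stop("'log2_offset' must be positive")
    if (any(values + log2_offset <= 0))
      stop("linear values must satisfy value + offset > 0")
    values <- log2(values + log2_offset)
  }
  structure(
    list(values = values,
         groups = factor(groups, levels = group_levels),
         log2_scale = TRUE),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("groups: ", paste(sprintf("%s (n=%d)", levels(x$groups),
                                tabulate(x$groups)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Split sample column indices by group; checks the two-group, n >= 2 contract
# shared by all variance-based tests.
two_group_index <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (nlevels(mat$groups) != 2L)
    stop("exactly two groups are required, got ", nlevels(mat$groups))
  idx <- split(seq_along(mat$groups), mat$groups)
  if (any(lengths(idx) < 2L))
    stop("each group needs at least 2 samples for variance-based tests")
  idx
}

#' Read an expression matrix and its sample-group map from TSV files
#'
#' @param path tab-delimited file: header row of sample ids, first column
#'   feature ids, numeric cells.
#' @param groups_path tab-delimited two-column file `sample_id<TAB>group` with
#'   a header row.
#' @param log2_scale,log2_offset,group_levels passed to [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, groups_path, log2_scale = TRUE,
                                   log2_offset = 1, group_levels = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("matrix file needs a feature-id column and >=1 sample")
  feat <- tab[[1L]]
  if (anyDuplicated(feat))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  num <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(num), dim = dim(num), dimnames = dimnames(num)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at feature '", feat[bad[1L]], "', sample '",
         colnames(num)[bad[2L]], "'")
  }
  rownames(vals) <- feat
  gr <- utils::read.delim(groups_path, check.names = FALSE, colClasses = "character")
  if (ncol(gr) < 2L) stop("groups file needs columns sample_id, group")
  groups <- stats::setNames(gr[[2L]], gr[[1L]])
  expression_matrix(vals, groups, log2_scale = log2_scale,
                    log2_offset = log2_offset, group_levels = group_levels)
}

#' Write an expression matrix (and optionally its group map) to TSV
#'
#' @param mat an `expression_matrix`.
#' @param path output file for the features x samples table.
#' @param groups_path optional output file for the sample/group map.
#' @export
write_expression_matrix <- function(mat, path, groups_path = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_report(df, path)
  if (!is.null(groups_path)) {
    write_report(data.frame(sample_id = names(mat$groups),
                            group = as.character(mat$groups),
                            stringsAsFactors = FALSE), groups_path)
  }
  invisible(NULL)
}
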