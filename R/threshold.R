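#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1 and mapped back to
#' the input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call up/down/ns from fold-change and significance thresholds
#'
#' A feature is called `up` if `log2_fc >= log2(fc_min)` and its (raw or
#' BH-adjusted) p-value is `<= p_max`; `down` with the opposite fold sign;
#' otherwise `ns`. Both cutoffs are inclusive.
#'
#' @param de a `de_table` (from [moderated_t()], [wilcoxon_de()] or built by
#'   hand) with columns `feature_id`, `log2_fc`, `p` and, if `use_q`, `q`.
#' @param fc_min minimum linear fold change, > 1 (e.g. 1.5).
#' @param p_max significance cutoff (e.g. 0.05).
#' @param use_q if `TRUE`, gate on the BH-adjusted `q` instead of raw `p`.
#' @return the input with a `call` factor column (`up`/`down`/`ns`).
#' @export
threshold_de <- function(de, fc_min = 1.5, p_max = 0.05, use_q = FALSE) {
  if (fc_min <= 1) stop("'fc_min' must exceed 1")
  stopifnot(all(c("feature_id", "log2_fc", "p") %in% names(de)))
  sig <- if (use_q) de$q <= p_max else de$p <= p_max
  lfc <- log2(fc_min)
  call <- rep("ns", nrow(de))
  call[sig & de$log2_fc >= lfc] <- "up"
  call[sig & de$log2_fc <= -lfc] <- "down"
  de$call <- factor(call, levels = c("up", "down", "ns"))
  de
}

# Convenience accessors for called feature sets.
de_up <- function(de) de$feature_id[de$call == "up"]
de_down <- function(de) de$feature_id[de$call == "down"]
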