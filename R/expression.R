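# Expression consequence of mis-splicing calls and gene-burden summaries.

#' Expression effect of a mutation relative to wild-type controls
#'
#' The control level is the mean expression of wild-type samples of the
#' same cancer type (samples with non-silent mutations, SV or CNA flags in
#' the gene are excluded by the caller); at least 5 wild-type samples are
#' required.
#'
#' @param mutant_expr Expression of the mutant sample (normalised scale).
#' @param wildtype_expr Numeric vector of wild-type sample expressions.
#' @param min_wildtype Minimum control count (default 5).
#' @return List `log2_ratio`, `n_wildtype`, `reason` (`NA` on success;
#'   `log2_ratio` is `NA` with reason `"too_few_wildtype"` otherwise).
#' @export
expression_effect <- function(mutant_expr, wildtype_expr, min_wildtype = 5L) {
  n <- length(wildtype_expr)
  if (n < min_wildtype)
    return(list(log2_ratio = NA_real_, n_wildtype = n,
                reason = "too_few_wildtype"))
  list(log2_ratio = log2(mutant_expr / mean(wildtype_expr)),
       n_wildtype = n, reason = NA_character_)
}

#' Compare expression effects between mutation classes
#'
#' Two-sided rank-sum (Mann-Whitney U) test on per-gene log2 ratios.
#'
#' @param x,y Numeric vectors of log2 ratios for the two classes.
#' @return List `p_value`, `median_x`, `median_y`.
#' @export
expression_class_compare <- function(x, y) {
  w <- wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(p_value = w$p.value, median_x = median(x), median_y = median(y))
}

#' Per-gene (and per-tissue) mutation-burden summary
#'
#' For each gene, the fraction of mutant tumour samples attributable to
#' each mutation class (e.g. intronic mis-splicing vs traditional
#' truncating), with an optional minimum-share filter on a class of
#' interest.
#'
#' @param calls `data.table(gene_id, sample_id, tissue, class)`; one row
#'   per (gene, sample, class) occurrence.
#' @param min_share Optional threshold: keep genes where `focus_class`
#'   accounts for more than this fraction of mutant samples.
#' @param focus_class Class used for the `min_share` filter (default
#'   `"intronic_missplicing"`).
#' @param by_tissue Also stratify by tissue (default `FALSE`).
#' @return `data.table` with per-gene sample counts per class,
#'   `n_mutant_samples` and `share_<class>` columns.
#' @export
gene_burden_summary <- function(calls, min_share = NULL,
                                focus_class = "intronic_missplicing",
                                by_tissue = FALSE) {
  dt <- as.data.table(calls)
  if (!nrow(dt)) return(dt)
  grp <- if (by_tissue) c("gene_id", "tissue") else "gene_id"
  cnt <- unique(dt[, c(grp, "sample_id", "class"), with = FALSE])
  tot <- cnt[, .(n_mutant_samples = uniqueN(sample_id)), by = grp]
  per <- cnt[, .(n = uniqueN(sample_id)), by = c(grp, "class")]
  wide <- dcast(per, paste(paste(grp, collapse = "+"), "~ class"),
                value.var = "n", fill = 0L)
  out <- merge(wide, tot, by = grp)
  for (cl in setdiff(names(wide), grp))
    out[[paste0("share_", cl)]] <- out[[cl]] / out$n_mutant_samples
  out <- out[n_mutant_samples > 0L]
  if (!is.null(min_share)) {
    col <- paste0("share_", focus_class)
    if (col %in% names(out)) out <- out[out[[col]] > min_share]
  }
  out[]
}
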