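# Allele-specificity validation. A mutation that truly drives an abnormal
# splicing event should have the variant allele overrepresented among the
# reads supporting the event (cryptic-site activation, intron retention),
# or underrepresented among reads covering a skipped exon. Both directions
# are assessed on 2x2 tables of read counts (rows DNA/RNA or
# spliced/unspliced, columns ref/alt) via the odds ratio; only the sign of
# log-OR relative to 1 is interpreted, so no continuity correction is used
# and zero cells follow explicit infinity/zero conventions.

#' Odds ratio of a 2x2 table with explicit zero-cell conventions
#'
#' @param table 2x2 non-negative integer matrix `[[a, b], [c, d]]`.
#' @return `(a*d)/(b*c)`; `+Inf` when `b*c == 0` with `a*d > 0`; `0` when
#'   `a*d == 0` with `b*c > 0`; `NA` (undefined) when both products are 0.
#' @export
odds_ratio <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  ad <- table[1L, 1L] * table[2L, 2L]
  bc <- table[1L, 2L] * table[2L, 1L]
  if (ad == 0 && bc == 0) return(NA_real_)
  if (bc == 0) return(Inf)
  ad / bc
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' Exact P by the probability-mass rule: with margins fixed, sum the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (relative tolerance 1e-7 for floating-point ties).
#'
#' @param table 2x2 non-negative integer matrix.
#' @return P value in `[0, 1]`.
#' @export
fisher_exact <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (sum(table) == 0L) stop("all-zero table")
  m <- table[1L, 1L] + table[2L, 1L]   # column 1 margin
  n <- table[1L, 2L] + table[2L, 2L]
  k <- table[1L, 1L] + table[1L, 2L]   # row 1 margin
  x <- table[1L, 1L]
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  d <- dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

contingency_result <- function(table, verdict, or = odds_ratio(table),
                               fisher_p = NA_real_, n_informative = NA_integer_) {
  structure(list(table = table, odds_ratio = or, fisher_p = fisher_p,
                 verdict = verdict, n_informative = n_informative),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> OR=%s verdict=%s\n",
              format(x$odds_ratio), x$verdict))
  invisible(x)
}

#' Allele-specificity test for cryptic splice-site activation
#'
#' Rows are DNA and RNA allele counts (RNA counted only among reads
#' supporting the cryptic site), columns ref and alt. Verifiable when at
#' least 3 informative RNA reads exist; variant-specific iff OR > 1.
#'
#' @param dna_counts `c(ref, alt)` tumour DNA allele counts.
#' @param rna_counts `c(ref, alt)` allele counts among cryptic-site reads.
#' @param min_reads Informative-read threshold (default 3).
#' @return A `contingency_result` with verdict `variant_specific` or
#'   `inconclusive`.
#' @export
cryptic_allele_test <- function(dna_counts, rna_counts, min_reads = 3L) {
  tab <- rbind(dna_counts, rna_counts)
  dimnames(tab) <- list(c("DNA", "RNA"), c("ref", "alt"))
  n_inf <- sum(rna_counts)
  if (n_inf < min_reads)
    return(contingency_result(tab, "inconclusive", n_informative = n_inf))
  or <- odds_ratio(tab)
  verdict <- if (!is.na(or) && or > 1) "variant_specific" else "inconclusive"
  contingency_result(tab, verdict, or, n_informative = n_inf)
}

#' Reference-allele-specific expression test for exon skipping
#'
#' For an exonic SNV on a skipped exon the variant allele should be
#' underrepresented among RNA reads covering the exon; verdict
#' `reference_specific` iff OR < 1 on the DNA/RNA x ref/alt table.
#'
#' @param dna_counts,rna_counts `c(ref, alt)` counts.
#' @return A `contingency_result`.
#' @export
skip_allele_test <- function(dna_counts, rna_counts) {
  tab <- rbind(dna_counts, rna_counts)
  dimnames(tab) <- list(c("DNA", "RNA"), c("ref", "alt"))
  if (sum(rna_counts) == 0L)
    return(contingency_result(tab, "inconclusive", n_informative = 0L))
  or <- odds_ratio(tab)
  verdict <- if (!is.na(or) && or < 1) "reference_specific" else "inconclusive"
  contingency_result(tab, verdict, or, n_informative = sum(rna_counts))
}

#' Allele-level confirmation of full intron retention
#'
#' Intronic variants: the retention reads must be variant-specific (OR > 1
#' against DNA counts), with at least `min_reads` variant-allele reads and
#' a variant-allele fraction above 80%. Exonic variants: Fisher exact test
#' on (spliced vs unspliced) x (ref vs alt) read counts, where unspliced
#' reads must span 5 bp of both exon and intron and carry at least
#' `min_reads` variant alleles; confirmation requires BH q < 0.1, applied
#' by the caller across the run (the exact P is returned here).
#'
#' @param category `"intronic"` or `"exonic"` branch.
#' @param dna_counts `c(ref, alt)` DNA counts (intronic branch).
#' @param retention_counts `c(ref, alt)` allele counts among retention
#'   reads (intronic branch).
#' @param spliced_counts,unspliced_counts `c(ref, alt)` RNA read counts
#'   (exonic branch).
#' @param min_reads Variant-allele read threshold (default 3).
#' @param min_fraction Variant-allele fraction threshold (default 0.8,
#'   exceeded strictly).
#' @return List `confirmed` (logical; `NA` for the exonic branch until the
#'   caller applies FDR), `reason`, and branch statistics (`odds_ratio`,
#'   `alt_fraction` or `fisher_p`).
#' @export
confirm_full_intron_retention <- function(category,
                                          dna_counts = NULL,
                                          retention_counts = NULL,
                                          spliced_counts = NULL,
                                          unspliced_counts = NULL,
                                          min_reads = 3L, min_fraction = 0.8) {
  if (category == "intronic") {
    stopifnot(!is.null(dna_counts), !is.null(retention_counts))
    tab <- rbind(dna_counts, retention_counts)
    or <- odds_ratio(tab)
    altn <- retention_counts[2L]
    frac <- if (sum(retention_counts) > 0) altn / sum(retention_counts) else NA
    ok_or <- !is.na(or) && or > 1
    confirmed <- ok_or && altn >= min_reads && !is.na(frac) &&
      frac > min_fraction
    reason <- if (confirmed) NA_character_
    else if (!ok_or) "not_variant_specific"
    else if (altn < min_reads) "too_few_alt_reads"
    else "alt_fraction_below_threshold"
    return(list(confirmed = confirmed, reason = reason, odds_ratio = or,
                alt_fraction = frac))
  }
  if (category == "exonic") {
    stopifnot(!is.null(spliced_counts), !is.null(unspliced_counts))
    if (unspliced_counts[2L] < min_reads)
      return(list(confirmed = FALSE, reason = "too_few_alt_unspliced",
                  fisher_p = NA_real_))
    tab <- rbind(spliced_counts, unspliced_counts)
    p <- fisher_exact(tab)
    return(list(confirmed = NA, reason = "pending_fdr", fisher_p = p))
  }
  stop("category must be 'intronic' or 'exonic'")
}

#' Rescue variants excluded by the ratio criteria using allele specificity
#'
#' A previously excluded variant is rescued when at least `min_reads`
#' abnormally spliced reads carry the variant allele, those make up more
#' than 80% of all abnormal reads, and (for distance-based exclusions) the
#' variant lies within `rescue_window` bp of the cryptic splice site.
#'
#' @param excluded `data.table` with columns `variant_id`, `reason`,
#'   `alt_abnormal` (variant-allele abnormal reads), `total_abnormal`, and
#'   `dist_to_cryptic`.
#' @param min_reads,min_fraction,rescue_window Thresholds (defaults 3,
#'   0.8, 100).
#' @return The rescued subset with a `rescued` flag.
#' @export
rescue_variants <- function(excluded, min_reads = 3L, min_fraction = 0.8,
                            rescue_window = 100L) {
  ex <- as.data.table(excluded)
  if (!nrow(ex)) { ex[, rescued := logical(0)]; return(ex) }
  frac_ok <- ex$alt_abnormal >= min_reads &
    ex$alt_abnormal / pmax(ex$total_abnormal, 1L) > min_fraction
  dist_ok <- ifelse(ex$reason == "distance",
                    !is.na(ex$dist_to_cryptic) &
                      abs(ex$dist_to_cryptic) <= rescue_window, TRUE)
  ex[, rescued := frac_ok & dist_ok]
  ex[rescued == TRUE]
}
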