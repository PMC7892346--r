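# Ratio-based detection: the abnormal/total junction-read ratio of the
# mutation-carrying sample is compared against two empirical background
# distributions of the same locus, one from a normal-tissue cohort and one
# from wild-type cancer samples. A call requires the observed ratio to lie
# strictly within the top 1% of both backgrounds and to survive
# Benjamini-Hochberg FDR < 0.1 on the normal-theory right-tail P of its
# Z-score (the larger of the two cohorts' right-tail P values is used,
# which is the conservative choice when the two backgrounds disagree).

#' Default detection configuration
#'
#' @param min_reads Minimum count of both normally and abnormally spliced
#'   reads for an eligible ratio (default 3).
#' @param min_cohort Minimum background cohort size (default 501, i.e. more
#'   than 500 samples).
#' @param top_pct Top-percentile gate on both backgrounds (default 0.01).
#' @param fdr FDR threshold (default 0.1).
#' @param window_junction,window_cryptic Candidate windows around authentic
#'   junctions and activated cryptic splice sites, bp (default 30).
#' @param rescue_window Allele-rescue distance from a cryptic site (default 100).
#' @param bp_window Branchpoint window, residues relative to the BP
#'   (default -5..+3).
#' @param nearby_bp Exclusion window for additional nearby variants (default 50).
#' @param nmd NMD-insensitivity bounds: first `nmd[1]` CDS nt and within
#'   `nmd[2]` nt upstream of the last exon-exon junction (default 250, 55).
#' @param n_perm Permutation count for enrichment tests (default 100000).
#' @param nu One-class SVM nu (default 0.05).
#' @param cv_folds,cv_iterations Cross-validation protocol (default 3, 1000).
#' @return Named list of thresholds, used throughout the pipeline.
#' @export
pipeline_config <- function(min_reads = 3L, min_cohort = 501L, top_pct = 0.01,
                            fdr = 0.1, window_junction = 30L,
                            window_cryptic = 30L, rescue_window = 100L,
                            bp_window = c(-5L, 3L), nearby_bp = 50L,
                            nmd = c(250L, 55L), n_perm = 100000L, nu = 0.05,
                            cv_folds = 3L, cv_iterations = 1000L) {
  as.list(environment())
}

#' Abnormal-splicing read ratio of one event
#'
#' @param abnormal_count,normal_count Non-negative read counts at the locus.
#' @param min_reads Eligibility threshold for both counts.
#' @return The ratio `abnormal / (abnormal + normal)`, or `NA` when either
#'   count is below `min_reads` (ineligible).
#' @export
event_ratio <- function(abnormal_count, normal_count, min_reads = 3L) {
  ifelse(abnormal_count >= min_reads & normal_count >= min_reads,
         abnormal_count / (abnormal_count + normal_count), NA_real_)
}

#' Build the dual background distribution of a locus
#'
#' @param support `data.table(sample_id, cohort, normal_count,
#'   abnormal_count)` for one locus; `cohort` is `"normal"` or `"cancer"`.
#' @param flagged_cancer Sample ids of cancer samples carrying non-silent
#'   mutations (or exonic SV breakpoints) in the gene; excluded from the
#'   cancer background.
#' @param min_reads Minimum normally-spliced reads for a sample to
#'   contribute its ratio.
#' @param min_cohort Minimum size of each background.
#' @return List of class `background_distribution`: per-cohort ratio
#'   vectors, sizes, means/SDs, and `testable` flag.
#' @export
build_background <- function(support, flagged_cancer = character(0),
                             min_reads = 3L, min_cohort = 501L) {
  s <- as.data.table(support)
  s <- s[!(cohort == "cancer" & sample_id %in% flagged_cancer)]
  s <- s[normal_count >= min_reads]
  rat <- function(co) {
    x <- s[cohort == co]
    x$abnormal_count / (x$abnormal_count + x$normal_count)
  }
  rn <- rat("normal"); rc <- rat("cancer")
  structure(list(
    normal_ratios = rn, cancer_ratios = rc,
    n_normal = length(rn), n_cancer = length(rc),
    mean_normal = mean(rn), sd_normal = sd(rn),
    mean_cancer = mean(rc), sd_cancer = sd(rc),
    testable = length(rn) >= min_cohort && length(rc) >= min_cohort),
    class = "background_distribution")
}

#' Test an observed ratio against a dual background
#'
#' Z-scores against each cohort, normal-theory right-tail P (the larger of
#' the two), and strict empirical top-percentile gates (type-7 quantile).
#'
#' @param ratio Observed abnormal-read ratio.
#' @param bg A `background_distribution`.
#' @param top_pct Gate percentile (default 0.01).
#' @return List `ratio, z_normal, z_cancer, p_value, top1_normal,
#'   top1_cancer, testable, reason`.
#' @export
test_event <- function(ratio, bg, top_pct = 0.01) {
  out <- list(ratio = ratio, z_normal = NA_real_, z_cancer = NA_real_,
              p_value = NA_real_, top1_normal = NA, top1_cancer = NA,
              testable = FALSE, reason = NA_character_)
  if (!isTRUE(bg$testable)) { out$reason <- "cohort_too_small"; return(out) }
  if (is.na(ratio)) { out$reason <- "ineligible_ratio"; return(out) }
  if (bg$sd_normal == 0 || bg$sd_cancer == 0) {
    out$reason <- "zero_background_sd"; return(out)
  }
  out$z_normal <- (ratio - bg$mean_normal) / bg$sd_normal
  out$z_cancer <- (ratio - bg$mean_cancer) / bg$sd_cancer
  out$p_value <- max(pnorm(out$z_normal, lower.tail = FALSE),
                     pnorm(out$z_cancer, lower.tail = FALSE))
  out$top1_normal <- ratio > quantile(bg$normal_ratios, 1 - top_pct,
                                      type = 7, names = FALSE)
  out$top1_cancer <- ratio > quantile(bg$cancer_ratios, 1 - top_pct,
                                      type = 7, names = FALSE)
  out$testable <- TRUE
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

#' Confounder filter: no other interpretable mutation in the gene
#'
#' Fails when the same sample carries another non-silent mutation (with the
#' 2-bp silent reclassification already applied), an exonic SV breakpoint in
#' the gene, or any additional variant within the nearby window.
#'
#' @param variant_pos 0-based position of the candidate variant.
#' @param gene_variants `data.table` of the sample's other variants in the
#'   gene with columns `pos` and `non_silent` (logical; effective silence).
#' @param sv_exonic_breakpoint Logical: gene carries an exonic SV breakpoint
#'   in this sample (supplied flag, not computed).
#' @param nearby_bp Nearby-variant window (default 50).
#' @return List `pass` (logical) and `reason`.
#' @export
confounder_filter <- function(variant_pos, gene_variants = NULL,
                              sv_exonic_breakpoint = FALSE, nearby_bp = 50L) {
  if (isTRUE(sv_exonic_breakpoint))
    return(list(pass = FALSE, reason = "sv_breakpoint_in_gene"))
  gv <- as.data.table(gene_variants)
  if (!is.null(gene_variants) && nrow(gv)) {
    gv <- gv[pos != variant_pos]
    if (nrow(gv)) {
      if (any(gv$non_silent))
        return(list(pass = FALSE, reason = "non_silent_in_gene"))
      if (any(abs(gv$pos - variant_pos) <= nearby_bp))
        return(list(pass = FALSE, reason = "nearby_variant"))
    }
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Candidate-window eligibility of a variant for the ratio analysis
#'
#' Eligible variants lie within 30 bp of an authentic exon-intron junction
#' or of an activated cryptic splice site. Deep intronic variants are
#' further restricted: they qualify only through a cryptic-site flank or a
#' branchpoint window (5 bp upstream to 3 bp downstream of a BP).
#'
#' @param location A location call from [classify_variant_location()].
#' @param dist_to_cryptic Distance in bp to the nearest activated cryptic
#'   splice site of the event (`NA` when none).
#' @param bp_relative Position of the variant relative to the nearest
#'   branchpoint (negative = upstream; `NA` when no BP annotated nearby).
#' @param window_junction,window_cryptic,bp_window Window sizes (see
#'   [pipeline_config()]).
#' @return Logical.
#' @export
candidate_window <- function(location, dist_to_cryptic = NA,
                             bp_relative = NA, window_junction = 30L,
                             window_cryptic = 30L, bp_window = c(-5L, 3L)) {
  near_cryptic <- !is.na(dist_to_cryptic) &&
    abs(dist_to_cryptic) <= window_cryptic
  if (location$category == "deep_intronic") {
    in_bp <- !is.na(bp_relative) && bp_relative >= bp_window[1L] &&
      bp_relative <= bp_window[2L]
    return(near_cryptic || in_bp)
  }
  abs(location$distance_bp) <= window_junction || near_cryptic
}
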