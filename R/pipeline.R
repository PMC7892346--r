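# End-to-end orchestration: sample QC -> variant prefilter -> event typing
# -> eligibility and confounder gates -> ratio test against dual cohort
# backgrounds -> FDR -> allele-specificity validation.

#' Run the mis-splicing detection pipeline on a cohort
#'
#' @param cohort A `sim_cohort` (or an equivalently shaped list built from
#'   external files: `support`, `reads`, `variants`, `junction_stats`,
#'   `splicing_factor_flags`, `genome` with `sequences`/`transcripts`/
#'   `bp_annotation`).
#' @param config From [pipeline_config()].
#' @return List of class `missplice_run`: `calls` (one row per
#'   variant-event with full detection and validation fields), `samples_kept`,
#'   `variants_kept`, `dropped_variants`, and `summary`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  genome <- cohort$genome
  kept_samples <- sample_qc(cohort$junction_stats,
                            cohort$splicing_factor_flags)
  pf <- prefilter_variants(cohort$variants)
  variants <- if (nrow(pf$kept)) pf$kept[sample_id %in% kept_samples]
  else pf$kept
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    rows <- c(rows, analyse_variant(v, cohort, config))
  }
  calls <- if (length(rows)) rbindlist(rows, fill = TRUE) else data.table()
  if (nrow(calls)) {
    fam <- calls$testable & calls$eligible & calls$confounder_pass
    calls[, fdr_q := NA_real_]
    if (any(fam)) calls$fdr_q[fam] <- bh_fdr(calls$p_value[fam])
    calls[, passed := testable & eligible & confounder_pass &
            top1_normal & top1_cancer & !is.na(fdr_q) & fdr_q < config$fdr]
    # full intron retention additionally requires allele-level confirmation
    calls[event_type == "full_intron_retention" & passed == TRUE,
          passed := fir_confirmed %in% TRUE]
    calls[, primary := FALSE]
    calls[!is.na(ratio),
          primary := ratio == max(ratio), by = variant_id]
  }
  summary <- list(
    n_samples_kept = length(kept_samples),
    n_variants_in = nrow(cohort$variants),
    n_variants_kept = nrow(variants),
    n_tests = if (nrow(calls)) sum(calls$testable & calls$eligible &
                                     calls$confounder_pass) else 0L,
    n_passed_calls = if (nrow(calls)) sum(calls$passed) else 0L,
    n_unique_passed_variants = if (nrow(calls))
      uniqueN(calls[passed == TRUE, variant_id]) else 0L)
  structure(list(calls = calls, samples_kept = kept_samples,
                 variants_kept = variants, dropped_variants = pf$dropped,
                 summary = summary, config = config),
            class = "missplice_run")
}

#' @export
print.missplice_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<missplice_run> %d/%d variants analysed, %d tests, ",
                     "%d passed calls (%d unique variants)\n"),
              s$n_variants_kept, s$n_variants_in, s$n_tests, s$n_passed_calls,
              s$n_unique_passed_variants))
  invisible(x)
}

analyse_variant <- function(v, cohort, config) {
  genome <- cohort$genome
  tid <- paste0(v$chrom, ".t1")
  isoforms <- Filter(function(t) t$chrom == v$chrom, genome$transcripts)
  if (!length(isoforms)) return(list())
  t <- select_longest_isoform(isoforms)
  known <- known_junctions(isoforms)
  seqs <- genome$sequences[[v$chrom]]
  loc <- classify_variant_location(v$pos, t)
  base_row <- data.table(
    variant_id = v$variant_id, gene_id = t$gene_id, sample_id = v$sample_id,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    location = loc$category, distance_bp = loc$distance_bp, side = loc$side)
  gr <- cohort$reads[sample_id == v$sample_id & gene_id == t$gene_id]
  if (!nrow(gr)) {
    return(list(no_event_row(base_row, "no_reads")))
  }
  cl <- classify_reads(gr, t, known)
  abn <- cl[class == "abnormal"]
  if (!nrow(abn)) {
    return(list(no_event_row(base_row, "no_abnormal_reads")))
  }
  events <- type_event(abn, t, known)
  events <- Filter(function(e) e$event_type != "combinatorial" ||
                     length(events) == 1L, events)
  out <- list()
  for (ev in events) {
    if (identical(ev$event_type, "combinatorial")) next
    ev <- locate_cryptic_sites(ev, seqs, t$strand,
                               list(pos = v$pos, ref = v$ref, alt = v$alt))
    cryp <- c(ev$cryptic_donor, ev$cryptic_acceptor)
    dist_cryp <- if (length(cryp)) min(abs(v$pos - cryp)) else NA_integer_
    # branchpoint context of the variant's intron
    bp_rel <- NA_integer_
    if (!is.null(loc$intron_idx)) {
      it <- transcript_introns(t)
      kv <- loc$intron_idx
      d_acc <- if (t$strand == "+") it$end[kv] - v$pos else v$pos - it$start[kv] + 1L
      bps <- cohort$genome$bp_annotation[chrom == v$chrom & intron_idx == kv]
      ann <- annotate_branchpoint(v$pos, d_acc, bps$pos, t$strand,
                                  config$bp_window)
      if (!is.null(ann)) bp_rel <- ann$relative
    }
    eligible <- candidate_window(loc, dist_cryp, bp_rel,
                                 config$window_junction,
                                 config$window_cryptic, config$bp_window)
    others <- cohort$variants[sample_id == v$sample_id & chrom == v$chrom &
                                variant_id != v$variant_id]
    conf <- confounder_filter(
      v$pos,
      if (nrow(others)) data.table(pos = others$pos,
                                   non_silent = variant_non_silent(others, t))
      else NULL,
      sv_exonic_breakpoint = FALSE, nearby_bp = config$nearby_bp)
    k <- ev$intron_idx
    n_normal <- sum(cl$class == "normal" & cl$intron_idx == k, na.rm = TRUE)
    n_abn <- ev$abnormal_count
    ratio <- event_ratio(n_abn, n_normal, config$min_reads)
    flagged <- flagged_cancer_samples(cohort, t)
    bg <- build_background(
      cohort$support[gene_id == t$gene_id & intron_idx == k], flagged,
      config$min_reads, config$min_cohort)
    res <- test_event(ratio, bg, config$top_pct)
    row <- copy(base_row)
    row[, `:=`(event_type = ev$event_type, intron_idx = k,
               cryptic_donor = ev$cryptic_donor %||% NA_integer_,
               cryptic_acceptor = ev$cryptic_acceptor %||% NA_integer_,
               pseudoexon_length = if (!is.null(ev$pseudoexon))
                 pseudoexon_bounds(ev)$length else NA_integer_,
               donor_origin = ev$donor_origin %||% NA_character_,
               audit_flag = isTRUE(ev$audit_flag),
               abnormal_count = n_abn, normal_count = n_normal,
               ratio = res$ratio, z_normal = res$z_normal,
               z_cancer = res$z_cancer, p_value = res$p_value,
               top1_normal = isTRUE(res$top1_normal),
               top1_cancer = isTRUE(res$top1_cancer),
               testable = res$testable, untestable_reason = res$reason,
               eligible = eligible, confounder_pass = conf$pass,
               dist_to_cryptic = dist_cryp, bp_relative = bp_rel)]
    row <- add_allele_validation(row, ev, v, cl, config)
    out[[length(out) + 1L]] <- row
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

no_event_row <- function(base_row, reason) {
  row <- copy(base_row)
  row[, `:=`(event_type = NA_character_, testable = FALSE,
             untestable_reason = reason, eligible = FALSE,
             confounder_pass = NA, p_value = NA_real_, ratio = NA_real_,
             top1_normal = FALSE, top1_cancer = FALSE)]
  row
}

variant_non_silent <- function(variants, t) {
  vapply(seq_len(nrow(variants)), function(i) {
    lc <- tryCatch(classify_variant_location(variants$pos[i], t),
                   error = function(e) NULL)
    if (is.null(lc)) return(FALSE)
    # intronic variants are silent at protein level; exonic coding status
    # is unknown here, so exonic variants are conservatively non-silent
    lc$category == "exonic"
  }, NA)
}

flagged_cancer_samples <- function(cohort, t) {
  vv <- cohort$variants[chrom == t$chrom]
  if (!nrow(vv)) return(character(0))
  unique(vv$sample_id[variant_non_silent(vv, t)])
}

add_allele_validation <- function(row, ev, v, cl, config) {
  row[, `:=`(allele_verdict = NA_character_, allele_or = NA_real_,
             fir_confirmed = NA, rna_ref = NA_integer_, rna_alt = NA_integer_)]
  dna <- c(v$dna_ref_count, v$dna_alt_count)
  if (ev$event_type %in% c("partial_intron_retention", "pseudoexon_activation")) {
    sup <- cl[class == "abnormal" & kind == "junction" & intron_idx == ev$intron_idx]
    rna <- rna_allele_counts(sup, v$pos, v$ref, v$alt)
    ct <- cryptic_allele_test(dna, rna[c("ref", "alt")], config$min_reads)
    row[, `:=`(allele_verdict = ct$verdict, allele_or = ct$odds_ratio,
               rna_ref = rna[["ref"]], rna_alt = rna[["alt"]])]
  } else if (ev$event_type == "full_intron_retention" &&
             row$location != "exonic") {
    sup <- cl[class == "abnormal" & kind == "unspliced_span" &
                intron_idx == ev$intron_idx]
    rna <- rna_allele_counts(sup, v$pos, v$ref, v$alt)
    fir <- confirm_full_intron_retention(
      "intronic", dna_counts = dna,
      retention_counts = rna[c("ref", "alt")],
      min_reads = config$min_reads)
    row[, `:=`(fir_confirmed = fir$confirmed, allele_or = fir$odds_ratio,
               allele_verdict = if (isTRUE(fir$confirmed)) "variant_specific"
               else "inconclusive",
               rna_ref = rna[["ref"]], rna_alt = rna[["alt"]])]
  }
  row
}

#' Null calibration of the top-percentile gates on a wild-type cohort
#'
#' For each locus, the abnormal-read ratios of held-out cancer samples are
#' tested against backgrounds built from the remaining samples: the
#' fraction of (query, locus) tests clearing both top-1% gates estimates
#' the pre-FDR operating point of the detector under the null, and BH over
#' the eligible tests counts false calls after FDR.
#'
#' @param cohort A `sim_cohort` (typically all-wild-type).
#' @param n_query Held-out cancer samples per locus (default 20).
#' @param config From [pipeline_config()].
#' @return List `tests` (per-query data.table), `gate_fraction`,
#'   `n_fdr_passes`, `n_tests`.
#' @export
null_gate_calibration <- function(cohort, n_query = 20L,
                                  config = pipeline_config()) {
  sup <- cohort$support
  loci <- unique(sup[, .(gene_id, intron_idx)])
  res <- list()
  cancer_ids <- unique(sup[cohort == "cancer", sample_id])
  queries <- head(cancer_ids, n_query)
  for (li in seq_len(nrow(loci))) {
    s <- sup[gene_id == loci$gene_id[li] & intron_idx == loci$intron_idx[li]]
    s_elig <- s[normal_count >= config$min_reads]
    rn <- s_elig[cohort == "normal",
                 abnormal_count / (abnormal_count + normal_count)]
    sc <- s_elig[cohort == "cancer"]
    for (q in queries) {
      qi <- which(sc$sample_id == q)
      if (!length(qi)) next
      qr <- sc$abnormal_count[qi] / (sc$abnormal_count[qi] + sc$normal_count[qi])
      elig <- sc$abnormal_count[qi] >= config$min_reads
      rc <- sc[-qi, abnormal_count / (abnormal_count + normal_count)]
      if (length(rn) < config$min_cohort || length(rc) < config$min_cohort)
        next
      zn <- (qr - mean(rn)) / sd(rn)
      zc <- (qr - mean(rc)) / sd(rc)
      res[[length(res) + 1L]] <- data.table(
        gene_id = loci$gene_id[li], intron_idx = loci$intron_idx[li],
        sample_id = q, ratio = qr, eligible = elig,
        top1_normal = qr > quantile(rn, 1 - config$top_pct, type = 7,
                                    names = FALSE),
        top1_cancer = qr > quantile(rc, 1 - config$top_pct, type = 7,
                                    names = FALSE),
        p_value = max(pnorm(zn, lower.tail = FALSE),
                      pnorm(zc, lower.tail = FALSE)))
    }
  }
  tests <- rbindlist(res)
  gate <- tests$eligible & tests$top1_normal & tests$top1_cancer
  q <- rep(NA_real_, nrow(tests))
  if (any(tests$eligible)) q[tests$eligible] <- bh_fdr(tests$p_value[tests$eligible])
  list(tests = tests, gate_fraction = mean(gate),
       n_fdr_passes = sum(gate & !is.na(q) & q < config$fdr),
       n_tests = nrow(tests))
}
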