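# Cohort simulation: background junction-support counts for every sample
# and locus, per-read evidence (with allele observations) for
# mutation-carrier loci, DNA allele counts, expression, and sample QC
# statistics.

#' Simulate a cohort of junction-read evidence with known ground truth
#'
#' @param genome A `sim_genome` (after [inject_mutations()] when a ledger
#'   is supplied, so that reference rewrites are reflected).
#' @param ledger Truth ledger from [inject_mutations()] (may be empty /
#'   `NULL` for an all-wild-type cohort).
#' @param config From [sim_config()]; defaults to the genome's config.
#' @param seed Integer seed.
#' @return List of class `sim_cohort`: `support` (`data.table(gene_id,
#'   intron_idx, sample_id, cohort, normal_count, abnormal_count)`),
#'   `reads` (evidence table rows for carrier sample/locus pairs),
#'   `variants`, `dna_counts` merged into `variants`, `junction_stats`,
#'   `splicing_factor_flags`, `expression` (`data.table(gene_id,
#'   sample_id, expr)`), `ledger`.
#' @export
simulate_cohort <- function(genome, ledger = NULL, config = genome$config,
                            seed = 1L) {
  set.seed(seed + 32452843L)
  gids <- names(genome$sequences)
  n_introns <- 4L
  normal_ids <- sprintf("N%04d", seq_len(config$n_normal_samples))
  cancer_ids <- sprintf("C%04d", seq_len(config$n_cancer_samples))
  loci <- CJ(gene_id = gids, intron_idx = seq_len(n_introns))
  samples <- data.table(
    sample_id = c(normal_ids, cancer_ids),
    cohort = rep(c("normal", "cancer"),
                 c(length(normal_ids), length(cancer_ids))))
  support <- loci[, .(sample_id = samples$sample_id, cohort = samples$cohort),
                  by = .(gene_id, intron_idx)]
  n <- nrow(support)
  tot <- rpois(n, config$coverage_mean)
  p_bg <- rbeta(n, config$bg_alpha, config$bg_beta)
  abn <- rbinom(n, tot, p_bg)
  support[, `:=`(abnormal_count = abn, normal_count = tot - abn)]

  reads_rows <- list()
  variants <- data.table()
  if (!is.null(ledger) && nrow(ledger)) {
    ledger <- copy(ledger)
    dna_depth <- rpois(nrow(ledger), config$dna_depth_mean)
    dna_alt <- rbinom(nrow(ledger), dna_depth, 0.5)
    variants <- data.table(
      variant_id = ledger$variant_id, chrom = ledger$chrom,
      pos = ledger$pos, ref = ledger$ref, alt = ledger$alt, kind = "SNV",
      sample_id = ledger$sample_id, gene_id = ledger$gene_id,
      dna_ref_count = dna_depth - dna_alt, dna_alt_count = dna_alt,
      caller_count = 3L, db_maf = NA_real_, cosmic_recurrence = 0L)
    for (j in seq_len(nrow(ledger))) {
      row <- ledger[j]
      t <- genome$transcripts[[paste0(row$gene_id, ".t1")]]
      rr <- carrier_reads(row, t, config)
      reads_rows[[length(reads_rows) + 1L]] <- rr$reads
      # overwrite the carrier's support counts at the event locus
      support[gene_id == row$gene_id & intron_idx == row$intron_idx &
                sample_id == row$sample_id,
              `:=`(abnormal_count = rr$abnormal, normal_count = rr$normal)]
    }
  }
  reads <- if (length(reads_rows)) rbindlist(reads_rows) else
    data.table(sample_id = character(), gene_id = character(),
               read_id = character(), kind = character(),
               junctions = character(), span = character(),
               var_pos = character(), var_base = character(),
               base_qual = character())

  junction_stats <- data.table(
    sample_id = samples$sample_id,
    cancer_type = rep_len(c("typeA", "typeB"), nrow(samples)),
    novel_junction_fraction = rbeta(nrow(samples), 2, 198))

  expr <- CJ(gene_id = gids, sample_id = cancer_ids)
  expr[, expr := 2 ^ rnorm(.N, log2(10), 0.3)]
  if (!is.null(ledger) && nrow(ledger)) {
    nmd_rows <- ledger[!is.na(ptc_expectation) & ptc_expectation == "sensitive"]
    for (j in seq_len(nrow(nmd_rows)))
      expr[gene_id == nmd_rows$gene_id[j] & sample_id == nmd_rows$sample_id[j],
           expr := expr * config$expr_nmd_factor]
  }
  structure(list(support = support, reads = reads, variants = variants,
                 junction_stats = junction_stats,
                 splicing_factor_flags = character(0),
                 expression = expr,
                 ledger = if (is.null(ledger)) data.table() else ledger,
                 genome = genome, config = config, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d support rows, %d carrier reads, %d variants\n",
              nrow(x$support), nrow(x$reads), nrow(x$variants)))
  invisible(x)
}

# evidence rows for one mutation-carrying sample at its event locus
carrier_reads <- function(row, t, config) {
  it <- transcript_introns(t)
  k <- row$intron_idx
  tot <- max(rpois(1L, config$coverage_mean), 6L)
  if (is.na(row$intended_event)) {
    p_bg <- rbeta(1L, config$bg_alpha, config$bg_beta)
    n_abn <- rbinom(1L, tot, p_bg)
  } else {
    n_abn <- rbinom(1L, tot, row$intended_ratio)
    n_abn <- max(n_abn, 0L)
  }
  n_norm <- tot - n_abn
  don <- it$donor_end[k]; acc <- it$acceptor_start[k]
  mk <- function(i, kind, junctions, span, covers_variant, abnormal) {
    var_base <- "."
    if (covers_variant) {
      var_base <- if (abnormal) {
        if (runif(1L) < row$allele_linkage) row$alt else row$ref
      } else row$ref
    }
    data.table(sample_id = row$sample_id, gene_id = row$gene_id,
               read_id = sprintf("%s_%s_%03d", row$variant_id,
                                 if (abnormal) "abn" else "nrm", i),
               kind = kind, junctions = junctions, span = span,
               var_pos = if (covers_variant) as.character(row$pos) else ".",
               var_base = var_base,
               base_qual = if (covers_variant)
                 as.character(config$base_quality) else ".")
  }
  ev <- row$intended_event
  abn_list <- lapply(seq_len(n_abn), function(i) {
    if (is.na(ev)) return(NULL)
    if (ev == "full_intron_retention") {
      # unspliced read over the junction nearest the variant
      b <- if (abs(row$pos - don) <= abs(row$pos - acc)) don else acc
      lo <- min(b - 12L, row$pos - 2L); hi <- max(b + 12L, row$pos + 2L)
      mk(i, "unspliced_span", ".", sprintf("%d-%d", lo, hi),
         covers_variant = TRUE, abnormal = TRUE)
    } else if (ev == "full_exon_skipping") {
      jx <- sprintf("%d-%d", don, it$acceptor_start[k + 1L])
      mk(i, "junction", jx, ".", covers_variant = FALSE, abnormal = TRUE)
    } else if (ev == "partial_intron_retention") {
      jx <- sprintf("%d-%d", don, row$cryptic_acceptor)
      mk(i, "junction", jx, ".",
         covers_variant = row$pos >= row$cryptic_acceptor, abnormal = TRUE)
    } else if (ev == "pseudoexon_activation") {
      jx <- sprintf("%d-%d;%d-%d", don, row$cryptic_acceptor,
                    row$cryptic_donor, acc)
      mk(i, "junction", jx, ".",
         covers_variant = row$pos >= row$cryptic_acceptor &&
           row$pos < row$cryptic_donor, abnormal = TRUE)
    }
  })
  nrm_list <- lapply(seq_len(n_norm), function(i) {
    mk(i, "junction", sprintf("%d-%d", don, acc), ".",
       covers_variant = FALSE, abnormal = FALSE)
  })
  list(reads = rbindlist(c(abn_list, nrm_list)),
       abnormal = n_abn, normal = n_norm)
}
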