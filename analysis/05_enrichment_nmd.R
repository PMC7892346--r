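#!/usr/bin/env Rscript
# Downstream characterisation: motif enrichment of the deep intronic
# mutation set by permutation, PTC/NMD classification of the intended
# aberrant transcripts, expression consequences, and a gene-burden view.

source("analysis/00_common.R")

st <- build_study()

## enhancer/silencer enrichment by permutation ------------------------------
led <- st$ledger
deep <- led[class %in% c("cryptic_donor_gain", "cryptic_acceptor_gain",
                         "cryptic_ppt_gain", "enhancer_gain",
                         "silencer_loss", "neutral")]
for (role in c("enhancer", "silencer")) {
  set <- st$genome$motif_sets[[role]]
  hit <- vapply(seq_len(nrow(deep)), function(j) {
    s <- st$genome$sequences[[deep$chrom[j]]]
    ms <- motif_scan(flank_11mer(s, deep$pos[j]),
                     flank_11mer(s, deep$pos[j], deep$alt[j]), set)
    if (role == "enhancer") ms$mut_hit && !ms$wt_hit
    else ms$wt_hit && !ms$mut_hit
  }, NA)
  names(hit) <- deep$variant_id
  seqs <- vapply(seq_len(nrow(deep)), function(j)
    flank_11mer(st$genome$sequences[[deep$chrom[j]]], deep$pos[j],
                deep$alt[j]), "")
  names(seqs) <- deep$variant_id
  obs_class <- if (role == "enhancer") "enhancer_gain" else "silencer_loss"
  obs <- deep[class == obs_class, variant_id]
  enr <- permutation_enrichment(obs, deep$variant_id, hit, sequences = seqs,
                                n_permutations = 100000L,
                                seed = STUDY_SEED + 7L)
  say("%s %s: observed %d unique-sequence hits among %d SNVs; P %s",
      obs_class, role, enr$observed_count, length(obs),
      if (enr$p_lt_min) sprintf("< %g", 1 / enr$n_permutations)
      else format(enr$p_value))
}

## PTC / NMD and expression -------------------------------------------------
nmd_tab <- led[!is.na(intended_event),
               .(variant_id, gene_id, class, intended_event, ptc_expectation)]
fwrite(nmd_tab, file.path(RESULTS_DIR, "nmd_classification.tsv"), sep = "\t")
say("PTC/NMD classes among effect mutations: %s",
    paste(sprintf("%s=%d", names(table(nmd_tab$ptc_expectation)),
                  table(nmd_tab$ptc_expectation)), collapse = ", "))

expr_rows <- lapply(seq_len(nrow(nmd_tab)), function(j) {
  row <- nmd_tab[j]
  e <- st$cohort$expression
  mut <- e[gene_id == row$gene_id &
             sample_id == led[variant_id == row$variant_id, sample_id], expr]
  wt <- e[gene_id == row$gene_id &
            sample_id != led[variant_id == row$variant_id, sample_id], expr]
  eff <- expression_effect(mut, wt)
  data.table(variant_id = row$variant_id, nmd = row$ptc_expectation,
             log2_ratio = eff$log2_ratio, n_wildtype = eff$n_wildtype)
})
expr_dt <- rbindlist(expr_rows)
fwrite(expr_dt, file.path(RESULTS_DIR, "expression_effects.tsv"), sep = "\t")
cmp <- expression_class_compare(expr_dt[nmd == "sensitive", log2_ratio],
                                expr_dt[nmd != "sensitive", log2_ratio])
say("NMD-sensitive vs other log2 expression ratios: medians %.2f vs %.2f, rank-sum P %.3g",
    cmp$median_x, cmp$median_y, cmp$p_value)

## gene burden --------------------------------------------------------------
burden_calls <- rbind(
  led[!is.na(intended_event),
      .(gene_id, sample_id, tissue = "pan", class = "intronic_missplicing")],
  # a synthetic truncating-mutation table for the comparison column
  data.table(gene_id = rep(names(st$genome$sequences)[1:10], each = 3),
             sample_id = sprintf("C%04d", 301:330), tissue = "pan",
             class = "truncating"))
b <- gene_burden_summary(burden_calls, min_share = 0.05)
fwrite(b, file.path(RESULTS_DIR, "gene_burden.tsv"), sep = "\t")
say("genes where intronic mis-splicing exceeds 5%% of mutant samples: %d",
    nrow(b))
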