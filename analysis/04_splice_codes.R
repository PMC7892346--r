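#!/usr/bin/env Rscript
# Splice-code alterations of the ground-truth mutations: donor/acceptor
# strength differences (mutant minus wild type), U2 duplex energy changes
# at branchpoints, and auxiliary motif gain/loss.

source("analysis/00_common.R")

st <- build_study()
models <- default_strength_models(st$genome)
sc <- score_truth_classes(st$genome, st$ledger, models)
fwrite(sc, file.path(RESULTS_DIR, "splice_code_scores.tsv"), sep = "\t")

summ <- sc[!is.na(metric),
           .(n = .N, mean_value = mean(value), min = min(value),
             max = max(value)), by = .(class, metric)]
fwrite(summ, file.path(RESULTS_DIR, "splice_code_summary.tsv"), sep = "\t")
print(summ)

say("strength losses negative: %.0f%%; gains positive: %.0f%%",
    100 * sc[grepl("disrupt|dinucleotide", class) & metric != "ddg_u2",
             mean(value < 0)],
    100 * sc[grepl("gain$", class) & metric %in%
               c("delta_donor", "delta_acceptor"), mean(value > 0)])
say("U2 duplex destabilised by BP disruptions: %.0f%%",
    100 * sc[metric == "ddg_u2", mean(value > 0)])

# PPT companion readout on the authentic acceptors
ppt <- vapply(st$genome$transcripts, function(t) {
  it <- transcript_introns(t)
  mean(vapply(seq_len(nrow(it)), function(k)
    ppt_pyrimidine_fraction(splice_site_window(
      st$genome$sequences[[t$chrom]], it$acceptor_start[k], "acceptor",
      t$strand)), 0))
}, 0)
say("mean authentic PPT pyrimidine fraction: %.2f", mean(ppt))
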