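#!/usr/bin/env Rscript
# Build the synthetic study: a 50-gene genome, 55 ground-truth somatic
# mutations covering every mechanism class, and a 600-normal/600-cancer
# cohort of junction-read evidence. Writes the study inputs in their
# standard on-disk formats.

source("analysis/00_common.R")

st <- build_study()
dir.create(file.path(RESULTS_DIR, "sim"), showWarnings = FALSE)

write_genome_fasta(st$genome, file.path(RESULTS_DIR, "sim", "genome.fa"))
write_gtf(st$genome$transcripts, file.path(RESULTS_DIR, "sim", "genes.gtf"))
fwrite(st$genome$bp_annotation,
       file.path(RESULTS_DIR, "sim", "branchpoints.tsv"), sep = "\t")
write_vcf(st$cohort$variants, file.path(RESULTS_DIR, "sim", "somatic.vcf"))
write_variants_tsv(st$cohort$variants,
                   file.path(RESULTS_DIR, "sim", "somatic.tsv"))
write_evidence_table(st$cohort$reads,
                     file.path(RESULTS_DIR, "sim", "carrier_reads.tsv"))
fwrite(st$cohort$support, file.path(RESULTS_DIR, "sim", "support.tsv"),
       sep = "\t")
fwrite(st$ledger, file.path(RESULTS_DIR, "sim", "truth_ledger.tsv"),
       sep = "\t")
writeLines(st$genome$motif_sets$enhancer$hexamers,
           file.path(RESULTS_DIR, "sim", "enhancers.txt"))
writeLines(st$genome$motif_sets$silencer$hexamers,
           file.path(RESULTS_DIR, "sim", "silencers.txt"))

say("genome: %d genes; %d ground-truth mutations (%d classes); cohort: %d samples",
    length(st$genome$sequences), nrow(st$ledger),
    uniqueN(st$ledger$class), uniqueN(st$cohort$support$sample_id))
say("evidence: %d background support rows, %d carrier reads",
    nrow(st$cohort$support), nrow(st$cohort$reads))
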