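# splicemut

Detection and characterisation of somatic intronic (and junction-proximal
exonic) mutations that disrupt mRNA splicing, from per-read junction
evidence in tumour transcriptomes.

Most splice-disrupting somatic mutations live outside the exome's
comfort zone: in canonical splice-site dinucleotides, the flanking
proximal intron, polypyrimidine tracts (PPT), branchpoints (BP), and deep
intronic positions where cryptic splice sites and auxiliary
enhancer/silencer elements decide whether a pseudoexon is spliced in.
`splicemut` is for computational biologists who want a desk-scale,
fully testable implementation of a cohort-based detection pipeline for
such mutations — with a synthetic-cohort generator carrying a ground-truth
ledger, so every statistical rule can be exercised end to end without
protected patient data.

## The method

For a mutation-carrying sample and locus, the event statistic is the
abnormal-read ratio

```
r = n_abnormal / (n_abnormal + n_normal),        n_abnormal, n_normal >= 3
```

where a read is *abnormal* if it spans a novel junction or covers an
exon–intron boundary unspliced by ≥ 5 bp on each side. The observed r is
referred to two empirical background distributions of the same locus —
one from > 500 normal samples, one from > 500 cancer samples without
interpretable mutations in the gene — via Z-scores and a right-tailed
normal P (the larger of the two). A call requires r strictly above the
empirical 99th percentile of **both** backgrounds and Benjamini–Hochberg
FDR < 0.1 over all eligible tests. Events are typed from junction
geometry (full/partial intron retention, full/partial exon skipping,
pseudoexon activation, combinatorial), candidate windows restrict
variants to ±30 bp of authentic junctions or activated cryptic sites
(deep intronic: BP windows −5..+3 or cryptic-site flanks), and every call
is validated by allele specificity: the odds ratio of the
(DNA vs RNA) × (ref vs alt) read-count table, OR > 1 for variant-specific
cryptic-site activation, OR < 1 for reference-specific expression of
skipped exons, with Fisher exact tests and explicit rescue rules for full
intron retention.

Downstream modules quantify the mechanism: position log-odds
donor/acceptor strength (9-mer and 23-mer windows, pluggable model
tables), U2 snRNA duplex energy at branchpoints (nearest-neighbour stack
table, motif `GUGUAGUA`), enhancer/silencer hexamer matching of ±5 bp
flanks with unique-sequence permutation enrichment, PTC detection on the
reconstructed aberrant transcript with the 250 nt / 55 nt NMD rule,
expression effects against ≥ 5 wild-type controls, gene-burden summaries,
and linear-kernel one-class SVM predictors (ν = 0.05) of proximal
mis-splicing variants from strength-difference features.

## A worked example

Simulate a 50-gene genome, inject fifteen mutations of three mechanism
classes, simulate a 600 normal + 600 cancer cohort, and run the pipeline:

```r
library(splicemut)
cfg    <- sim_config(effect_range = c(0.2, 0.6))
genome <- generate_genome(cfg, seed = 1)
inj    <- inject_mutations(genome, rep(c("donor_disrupt", "bp_disrupt",
                                         "cryptic_donor_gain"), each = 5),
                           seed = 2)
cohort <- simulate_cohort(inj$genome, inj$ledger, cfg, seed = 3)
run    <- run_pipeline(cohort)
run
#> <missplice_run> 14/15 variants analysed, 14 tests, 14 passed calls (14 unique variants)
run$calls[passed == TRUE & primary == TRUE,
          .(variant_id, event_type, ratio = round(ratio, 3),
            z_cancer = round(z_cancer, 1), fdr_q = signif(fdr_q, 3),
            allele_verdict)]
#>     variant_id               event_type ratio z_cancer    fdr_q   allele_verdict
#>  1:       v001    full_intron_retention 0.216     10.9 2.94e-27 variant_specific
#>  2:       v002    full_intron_retention 0.294     12.4 1.15e-35 variant_specific
#>  3:       v004    full_intron_retention 0.214     10.2 1.63e-24 variant_specific
#>  4:       v005    full_intron_retention 0.717     20.7 1.40e-94 variant_specific
#>  5:       v006 partial_intron_retention 0.488     17.1 9.82e-66 variant_specific
#>  ...
#> 14:       v015    pseudoexon_activation 0.316     13.2 4.71e-40 variant_specific
```

One of the fifteen carriers was removed by the cohort's novel-junction
sample QC, so fourteen variants were analysed. Each recovered call shows
the injected event type: donor disruptions retain their intron,
branchpoint disruptions splice to a cryptic acceptor (partial retention),
and cryptic-donor gains splice in a pseudoexon; abnormal ratios of
0.18–0.72 sit 8–21 cancer-background SDs above the locus background, and
every cryptic-site call is allele-validated (all event-supporting reads
carry the variant allele, so OR = ∞ > 1).

The numbered scripts under `analysis/` run the full study the same way —
`01_simulate` writes the inputs (FASTA/GTF/VCF/TSV), `02_detect` the
calls, `03_null_calibration` the wild-type calibration,
`04_splice_codes` strength and U2-energy tables, `05_enrichment_nmd`
motif enrichment, PTC/NMD and expression effects, `06_prediction` the
one-class models — each writing tables under `results/`.

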