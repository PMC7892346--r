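---
title: "Detecting somatic mis-splicing mutations from junction-read ratios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mis-splicing mutations from junction-read ratios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemut)
library(data.table)
```

## The problem

Somatic mutations in introns can derail pre-mRNA splicing: they weaken the
donor or acceptor splice sites (SS), the polypyrimidine tract (PPT) or the
branchpoint (BP), or they create cryptic splice sites and alter splicing
enhancers/silencers deep inside introns. The transcriptomic consequences —
intron retention, exon skipping, pseudoexon activation — can inactivate
tumour suppressors just as effectively as coding mutations, yet most of
these variants are invisible to exome-centric analyses. `splicemut`
implements a detection-and-characterisation pipeline for such mutations
from per-read splicing evidence, together with a synthetic-cohort
generator that makes every statistical rule testable without access to
protected patient data.

## The ratio test

For a sample and locus (an intron of a gene), reads are classified as
*normally spliced* (every junction they span is annotated) or *abnormally
spliced* (a novel junction, or unspliced coverage across an exon–intron
boundary of at least 5 bp on each side). The event statistic is

$$ r = \frac{n_\text{abnormal}}{n_\text{abnormal} + n_\text{normal}}, $$

eligible only when both counts are at least 3. The observed ratio of a
mutation-carrying sample is compared against two empirical background
distributions of the same locus — one from a normal-tissue cohort, one
from cancer samples without interpretable mutations in the gene — each
required to have more than 500 contributing samples with at least 3
normally spliced reads. The observed ratio is transformed into a Z-score
against each background and a right-tailed normal P value is taken (the
larger of the two, the conservative choice when the cohorts disagree). A
call requires the ratio to lie strictly above the empirical 99th
percentile (type-7 quantile) of *both* backgrounds and to survive
Benjamini–Hochberg FDR < 0.1 across all eligible (variant, event) tests
in the run.

Candidate variants are restricted to windows where a splicing effect is
mechanistically interpretable: within 30 bp of an authentic exon–intron
junction or of an activated cryptic splice site; deep intronic variants
(more than 20 bp from any junction) qualify only through a cryptic-site
flank or a branchpoint window (5 bp upstream to 3 bp downstream of an
annotated BP). Variants are dropped when the same gene carries another
non-silent mutation in that sample (silent exonic SNVs within 2 bp of a
junction are reclassified non-silent), an exonic structural-variant
breakpoint, or any additional variant within 50 bp. The 50 bp
nearby-variant window is a reconstruction — the source analysis does not
state its exact value — and is configurable.

### Event typing

Abnormal junction geometry determines the event class: a novel junction
from an annotated donor to an intra-intron acceptor (or the mirror case)
is partial intron retention with one cryptic site; the complementary pair
of novel junctions bracketing an internal interval is pseudoexon
activation (both junctions must be read-supported; one-sided support is
flagged); a junction joining two annotated boundaries across one or more
whole exons is full exon skipping; a junction truncating an annotated
exon is partial exon skipping; unspliced retention evidence with no novel
junction is full intron retention; two or more distinct geometries at one
locus are combinatorial. Pseudoexons and retained segments shorter than
10 bp are treated as alignment artifacts. Cryptic donors must begin `GT`
in the reference (or become `GT` through the variant, the GC→GT
conversion); cryptic acceptors must be preceded by a reference `AG`;
violations raise an audit flag rather than an error.

### Allele-specificity validation

A causal variant should be physically linked to the aberrant reads. For
cryptic-site events, the 2×2 table of (DNA vs RNA) × (reference vs
variant allele) read counts — RNA counted only among reads supporting the
cryptic site, with base quality ≥ 30 and at least 3 informative reads —
is summarised by its odds ratio; OR > 1 is variant-specific splicing.
For skipped exons the direction reverses: OR < 1 is reference-specific
expression of the skipped exon. Full intron retention is confirmed at the
allele level: OR > 1, at least 3 variant-allele retention reads, and a
variant-allele fraction above 80% (intronic variants), or a Fisher exact
test on (spliced vs unspliced) × (ref vs alt) with BH q < 0.1 (exonic
variants). Only the sign of the OR is interpreted, so zero cells follow
explicit conventions (`+Inf`, `0`, undefined) and no continuity
correction is applied. Variants excluded by the ratio criteria can be
rescued when ≥ 3 variant-allele abnormal reads make up more than 80% of
abnormal reads within 100 bp of the cryptic site.

## Splice-code scoring

Splice-site strength is scored by a smoothed position log-odds model:
windows are 3 exonic + 6 intronic bases for donors (9-mer) and 20
intronic + 3 exonic for acceptors (23-mer), and the score is
$\sum_i \log_2(p_i(b_i)/0.25)$ with add-one smoothing
$p_i(b) = (c_i(b)+1)/(n+4)$ estimated from a supplied set of authentic
junction windows. The default model is trained on the annotation's own
junctions; externally supplied per-position probability tables (for
example, exported maximum-entropy marginals) load through the same
interface, so the scorer is pluggable. Scores are in log2-odds units
against a uniform background: 0 is uninformative, higher is stronger.
Effects of variants are reported as `delta = score(mutant) −
score(wild-type)`; for cryptic-site gains the score is also compared with
the corresponding authentic site. Because the acceptor window has 23
positions, a very strong PPT consensus would inflate acceptor scores far
above the donor scale; the generator therefore uses a moderate authentic
PPT pyrimidine content (0.72), keeping both sides on a comparable scale —
as in calibrated strength models — so that cross-site differences (used
as prediction features) are meaningful. A PPT companion readout, the
pyrimidine fraction of the intronic −20..−4 region, is exposed alongside
the 23-mer score.

U2 snRNA recognition of the branchpoint is summarised as a duplex energy
between the 8 residues flanking the BP (5 upstream, 3 downstream, the
bulged BP adenosine excluded) and the U2 motif `GUGUAGUA`, using a
bundled nearest-neighbour stack table over Watson–Crick and G·U pairs
with a +1 kcal/mol penalty per mismatched position. The table values are
representative magnitudes, not measured parameters: every analysis built
on this score interprets only signs and orderings of ΔΔG = ΔG(mutant) −
ΔG(wild-type), for which the table guarantees that any single mutation of
the perfect complement strictly raises ΔG. Variants are annotated to the
nearest BP only when 15–60 bp from the acceptor junction, ties broken to
the lower genomic coordinate.

Auxiliary codes are handled as hexamer sets: the ±5 bp flanks of an SNV
give an 11-mer whose six hexamer frames are matched against
enhancer/silencer sets separately for each allele, a sequence counting
once per set regardless of how many hexamers match. Enrichment of an
observed SNV set is assessed by drawing equally sized sets from a stated
SNV universe (100,000 permutations by default; exhaustive enumeration for
tiny universes), with identical 11-mers de-duplicated before counting.
The permutation P is the proportion of draws with at least the observed
count; when no draw reaches it, the result records that P < 1/n rather
than 0.

## PTC and NMD

For each passed event the aberrant mature mRNA is reconstructed (the
highest-ratio form when several forms of one event type exist; the
longest isoform when several isoforms show the event), translated from
the annotated start codon, and scanned for the first in-frame stop
upstream of the annotated stop. PTC positions are measured in CDS
coordinates of the aberrant transcript — the frame in which the PTC
exists. PTCs within the first 250 CDS nt, or from 55 nt upstream of the
last exon–exon junction to the end of the last exon, are NMD-insensitive;
all others are NMD-sensitive. Single-exon transcripts are insensitive (no
junction to assemble an exon-junction complex); UTR-only events are not
classified; combinatorial events whose sub-events disagree are excluded
as inconsistent. Expression consequences are quantified as the log2 ratio
of the mutant sample to the mean of at least five wild-type samples of
the same cancer type, with classes compared by a two-sided rank-sum test.

## One-class prediction models

Three model classes cover the proximal positions with a high rate of
abnormal splicing: donor intronic (+3..+6), donor exonic (−2..−1) and
acceptor intronic (+3). Each variant is summarised by two strength
differences at its authentic sites — donor models use
(donor~MUT~ − donor~WT~, donor~MUT~ − acceptor~WT~), the acceptor model
the mirror pair — and a linear-kernel one-class SVM with ν = 0.05 learns
the boundary of the mis-splicing cloud. Performance is evaluated by
repeated 3-fold cross-validation (1000 iterations in full runs); since
only positives exist, fold "accuracy" is the held-out inlier rate
(sensitivity), reported both over all folds and over per-iteration means.
The comparator model is trained on the same number of randomly selected
SNVs at the corresponding sites.

Two numerical choices matter here. First, features are scaled by the
training standard deviation but **not centred**: a linear one-class SVM
separates its training cloud from the origin, and the signal is precisely
the coherent offset of mis-splicing strength losses from zero — centring
would place any cloud at the origin and degenerate the boundary. This is
also what makes the mis-splicing/random contrast work: random-site deltas
straddle zero, so their cloud offers the SVM no margin and cross-validated
accuracy collapses, while the coherent mis-splicing cloud is captured at
the ν operating point. Second, predictions threshold the decision value
with a tolerance proportional to its scale, because duplicated training
points form margin clusters whose decision values land within the
optimiser's termination tolerance of zero.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions of the validation suite. Each gene is a plus-strand five-exon
coding transcript on its own contig with consensus splice codes: donors
`MAG|GT RAGT`-like (the exonic −1 fixed to G), acceptors with a PPT,
pyrimidine −3 and `AG`, exonic +1 fixed to G, and a U2-complementary
branchpoint context (`TACTAACAC`) 24–32 bp upstream of each acceptor.
Three planted deep-intronic features give every mutation class a feasible
site: a pseudoexon cassette with a strong acceptor and a weak
pre-existing-GT donor (intron 2), a deep weak-acceptor `AG` (intron 3),
and a cassette carrying a planted silencer hexamer and a near-miss
enhancer hexamer (intron 4). Motif contexts are T-free outside the
hexamer while every random motif-set member carries at least two T
residues, so motif gain/loss is decided by the intended edit alone.

Background mis-splicing is drawn per sample and locus as
$p \sim \mathrm{Beta}(1, 99)$ (mean 1%), with read counts binomial at
Poisson coverage (mean 40 informative reads); cohort sizes default to 600
normal and 600 cancer samples so every locus clears the >500-sample
requirement. Mutation-carrying samples draw their abnormal ratio from a
configurable effect law (default Uniform(0.15, 0.6); the validation runs
use 0.2–0.6), and abnormal reads carry the variant allele at a
configurable linkage fidelity (default 1). DNA allele counts are binomial
around 0.5 VAF at Poisson depth 60. Genes whose intended event yields an
NMD-sensitive PTC have the carrier's expression multiplied by 0.5.
Background evidence is emitted at junction-support count level, and
per-read observations (the level at which every read rule applies) for
carrier sample/locus pairs: emitting ~2.4 million background read rows
per cohort would exercise no rule that the counts do not.

What the generator does **not** emulate: alignment and base-calling error,
PCR duplicates, multi-isoform genes, minus-strand genes (the coordinate
machinery supports both strands and is tested on mirrored fixtures, but
cohorts are plus-strand), heavy-tailed per-locus background families,
tumour purity and subclonality. Passing tests therefore demonstrate the
correctness and calibration of the statistical rules under the stated
read model, not robustness to alignment artifacts in real data.

## Calibration findings and known limitations

On all-wild-type cohorts, the fraction of held-out (query, locus) tests
clearing both top-1% gates is ~0.9% — the designed pre-FDR operating
point — and a cohort without somatic variants never produces a call. A
caveat the analysis scripts make explicit: under the right-skewed
Beta-binomial background, the normal-theory right-tail P overstates the
significance of ratios in the extreme tail, so gate-passing null queries
would also survive BH FDR if they entered the test family. Specificity
against null loci is therefore carried by the strict empirical
top-percentile gates on both cohorts and the candidate-window and
eligibility rules, with the FDR step operating on the anti-conservative P
values only within the gated family. Users applying the pipeline to
backgrounds far heavier-tailed than Beta(1, 99) should treat the reported
P values as ordering scores rather than calibrated tail probabilities.

The discrete permutation P (`proportion ≥ observed`) is intrinsically
slightly super-uniform — by half the tie probability at the observed
count — which is visible in uniformity checks whenever the null count
support is coarse; enrichment tests should use universes and set sizes
large enough for a fine-grained count distribution.

Other reconstructions a reader should know about (the source analysis
leaves them unstated): intronic positions are numbered +1 at the first
intronic base on each side, with donor/acceptor side recorded separately;
equal-length isoforms tie-break to the smallest transcript id; deletions
are located by their 5′-most deleted base; the sample-QC z-score uses the
population SD within each cancer type; the single reported P per event is
the maximum of the two cohort right-tail P values; and per-event
read-counting rules follow the junction-geometry reconstruction described
above.

## Problem sizes

The validation suite runs, per invocation: a 50-gene, 600+600-sample
cohort with 50 injected mutations for parameter recovery; one all-wild-type
cohort with 20 held-out queries per locus (4000 null tests) plus 20
variant-free replicate cohorts for calibration; 3-fold × 100-iteration
cross-validation on 60 feature vectors for the one-class models; and 500
permutation-test datasets at 10,000 permutations for the uniformity check.
These sizes were chosen to give stable estimates (binomial standard errors
at or below a percentage point on the reported fractions) at desk scale.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(effect_range = c(0.2, 0.6))
genome <- generate_genome(cfg, seed = 1)
inj <- inject_mutations(genome, rep(c("donor_disrupt", "bp_disrupt",
                                      "cryptic_donor_gain"), each = 5),
                        seed = 2)
cohort <- simulate_cohort(inj$genome, inj$ledger, cfg, seed = 3)
run <- run_pipeline(cohort)
run$calls[passed == TRUE & primary == TRUE,
          .(variant_id, event_type, ratio, fdr_q, allele_verdict)]
```

The numbered scripts under `analysis/` run the same machinery as a full
study — simulation, detection, null calibration, splice-code scoring,
enrichment/NMD/expression, and prediction — writing their tables under
`results/`.
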