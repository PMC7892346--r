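# Synthetic cohorts with known ground truth. The generator emulates the
# data model the pipeline consumes: a small genome of multi-exon genes with
# consensus-bearing donor/acceptor sites, polypyrimidine tracts and
# U2-complementary branchpoints; somatic single-base edits implementing the
# mutation mechanism classes; and per-sample junction-read evidence in
# which mutation-carrying samples show an elevated abnormal-read ratio
# linked to the variant allele. Background mis-splicing per sample and
# locus follows Beta(1, 99) (mean 1%) with binomial read sampling at
# Poisson coverage; cohort sizes default to 600 normal + 600 cancer
# samples so that every locus clears the >500-sample background
# requirement.
#
# Background evidence is emitted at junction-support count level; per-read
# observations (with allele information) are emitted for mutation-carrier
# sample/locus pairs, which is where every read-level rule applies.

#' Simulation configuration
#'
#' Defaults are the study conditions of the package's validation suite.
#'
#' @param n_genes Number of genes (one contig each).
#' @param n_normal_samples,n_cancer_samples Cohort sizes (defaults 600;
#'   both must exceed 500 for loci to be testable).
#' @param bg_alpha,bg_beta Beta law of the per-sample background
#'   abnormal-splicing probability (defaults 1, 99: mean 0.01).
#' @param coverage_mean Poisson mean of informative reads per locus and
#'   sample (default 40).
#' @param dna_depth_mean Poisson mean of DNA depth at variant positions
#'   (default 60).
#' @param effect_range Injected abnormal-read ratio range for mutant
#'   samples (default `c(0.15, 0.6)`, drawn uniformly).
#' @param fidelity Allele-linkage fidelity: probability that an abnormal
#'   read carries the variant allele (default 1).
#' @param base_quality Base quality attached to simulated allele
#'   observations (default 37).
#' @param expr_nmd_factor Expression multiplier applied to carrier samples
#'   of NMD-sensitive events (default 0.5).
#' @param n_exons Exons per gene (default 5).
#' @return Named list.
#' @export
sim_config <- function(n_genes = 50L, n_normal_samples = 600L,
                       n_cancer_samples = 600L, bg_alpha = 1, bg_beta = 99,
                       coverage_mean = 40, dna_depth_mean = 60,
                       effect_range = c(0.15, 0.6), fidelity = 1.0,
                       base_quality = 37L, expr_nmd_factor = 0.5,
                       n_exons = 5L) {
  as.list(environment())
}

MUTATION_CLASSES <- c("donor_disrupt", "ss_dinucleotide", "acceptor_disrupt",
                      "ppt_disrupt", "bp_disrupt", "cryptic_donor_gain",
                      "cryptic_acceptor_gain", "cryptic_ppt_gain",
                      "enhancer_gain", "silencer_loss", "neutral")

# fixed intron layout (0-based offsets within each intron)
INTRON_LEN <- c(300L, 400L, 300L, 400L)
# cassette layout inside introns 2 and 4 (length 400): acceptor PPT at
# 150..163, AG at 164..165, pseudoexon [166, 260), donor GT at 260..261
PE_PPT <- 150L; PE_ACC <- 166L; PE_DON <- 260L
# deep cryptic acceptor in intron 3 (length 300): weak PPT, AG at 198..199,
# first retained base at 200
DEEP_ACC <- 200L
# mini acceptor for branchpoint-disruption rescue events in intron 1
# (length 300): AG ends 45 bp upstream of the authentic acceptor
MINI_ACC_FROM_END <- 45L
# planted auxiliary motifs inside the intron-4 cassette
SIL_OFF <- 233L   # exact silencer hexamer at 233..238
ENH_OFF <- 245L   # near-miss enhancer hexamer at 245..250
ENHANCER_HEX <- "GAAGAA"; ENHANCER_NEARMISS <- "GATGAA"  # pos 3 T->A completes
SILENCER_HEX <- "TAGGGT"; SILENCER_BROKEN <- "TAGCGT"    # pos 4 G->C breaks
# The 11-mer contexts around the planted motif variants are T-free outside
# the hexamer (flanks drawn from A/C/G, varying per gene), and every random
# member of the synthetic motif sets carries at least two T residues: no
# frame that straddles a planted hexamer and its flank can accidentally
# match a set member, so motif gain/loss is decided by the intended edit.
rand_acg <- function(n) paste(sample(c("A", "C", "G"), n, replace = TRUE),
                              collapse = "")
sil_context <- function() paste0(rand_acg(2L), SILENCER_HEX, rand_acg(3L))
enh_context <- function() paste0(rand_acg(3L), ENHANCER_NEARMISS, rand_acg(2L))

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

sample_weighted <- function(choices, probs) sample(choices, 1L, prob = probs)

# donor intronic consensus sampler for +3..+6 (after the fixed GT)
sample_donor_tail <- function() {
  paste0(sample_weighted(c("A", "G", "C", "T"), c(.60, .25, .075, .075)),
         sample_weighted(c("A", "G", "C", "T"), c(.70, .10, .10, .10)),
         sample_weighted(c("G", "A", "C", "T"), c(.80, .08, .06, .06)),
         sample_weighted(c("T", "A", "C", "G"), c(.55, .15, .15, .15)))
}

sample_ppt <- function(n, pyr = 0.85) {
  paste(ifelse(runif(n) < pyr, sample(c("C", "T"), n, replace = TRUE),
               sample(c("A", "G"), n, replace = TRUE)), collapse = "")
}

build_intron <- function(L, role, bp_dist) {
  s <- strsplit(rand_dna(L), "")[[1L]]
  set_seq <- function(off, str) {
    b <- strsplit(str, "")[[1L]]
    s[(off + 1L):(off + length(b))] <<- b
  }
  set_seq(0L, paste0("GT", sample_donor_tail()))
  # branchpoint context: TACTA + A(BP) + CAC, BP at bp_dist from acceptor
  bp_off <- L - bp_dist
  set_seq(bp_off - 5L, "TACTAACAC")
  # acceptor side: PPT (-20..-4), pyrimidine -3, AG. Moderate pyrimidine
  # content keeps acceptor scores on the donor scale (23 positions would
  # otherwise dominate every cross-site strength difference)
  set_seq(L - 20L, sample_ppt(17L, pyr = 0.72))
  set_seq(L - 3L, sample(c("C", "T"), 1L))
  set_seq(L - 2L, "AG")
  if (role == "cassette") {
    set_seq(PE_PPT, sample_ppt(14L, pyr = 0.95))
    set_seq(PE_ACC - 2L, "AG")
    set_seq(PE_DON - 1L, "A")                      # weak donor -1
    set_seq(PE_DON, paste0("GT", "AAGT"))          # pre-existing GT, strong tail
  }
  if (role == "cassette_motif") {
    set_seq(PE_PPT, sample_ppt(14L, pyr = 0.95))
    set_seq(PE_ACC - 2L, "AG")
    set_seq(PE_DON - 1L, "G")                      # strong donor
    set_seq(PE_DON, paste0("GT", "AAGT"))
    set_seq(SIL_OFF - 2L, sil_context())
    set_seq(ENH_OFF - 3L, enh_context())
  }
  if (role == "mini_acceptor") {
    off <- L - MINI_ACC_FROM_END - 8L   # TTTCTT + AG, AG ends at L-45
    set_seq(off, "TTTCTTAG")
  }
  if (role == "deep_acceptor") {
    set_seq(DEEP_ACC - 18L, sample_ppt(15L, pyr = 0.55))
    set_seq(DEEP_ACC - 3L, "A")                    # weak -3 (purine)
    set_seq(DEEP_ACC - 2L, "AG")
    set_seq(DEEP_ACC, "A")                         # weak +1, gain target
  }
  paste(s, collapse = "")
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b), 1L, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA", "ATG"))
})

#' Generate a synthetic genome with annotation and branchpoints
#'
#' Every gene is a plus-strand, five-exon coding transcript on its own
#' contig, with consensus donors (GT RAGT), polypyrimidine tracts and
#' AG acceptors, a U2-complementary branchpoint 24-32 bp upstream of each
#' acceptor, and planted deep-intronic features used by the mutation
#' injector: a pseudoexon cassette with a weak pre-existing GT donor
#' (intron 2), a deep weak acceptor AG (intron 3), and a cassette carrying
#' planted splicing-silencer and near-miss enhancer hexamers (intron 4).
#' Internal exons start with G, the exonic acceptor consensus.
#'
#' @param config From [sim_config()].
#' @param seed Integer seed; the genome is a deterministic function of
#'   `(config, seed)`.
#' @return List of class `sim_genome`: `sequences` (named character),
#'   `transcripts` (list of `transcript_model`), `bp_annotation`
#'   (data.table `chrom, pos, source, intron_idx`), `motif_sets`
#'   (enhancer/silencer `motif_set`s), and `features` (per-gene planted
#'   feature coordinates used by [inject_mutations()]).
#' @export
generate_genome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n_exons <- config$n_exons
  stopifnot(n_exons == 5L)  # the planted intron layout assumes 5 exons
  seqs <- character(0); transcripts <- list(); feats <- list()
  bp_rows <- list()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("g%03d", g)
    tid <- paste0(gid, ".t1")
    # mRNA: 30 nt 5'UTR, 160-codon CDS (ATG..stop), 90 nt 3'UTR
    n_codons <- 160L
    cds <- paste0("ATG", paste(sample(NON_STOP_CODONS, n_codons - 2L,
                                      replace = TRUE), collapse = ""), "TAA")
    mrna <- paste0(rand_dna(30L), cds, rand_dna(90L))
    mlen <- nchar(mrna)                      # 603
    bounds <- cumsum(c(120L, 120L, 120L, 120L))
    exon_mlens <- diff(c(0L, bounds, mlen))
    # junction-flanking exonic consensus: exons end with G (the MAG|GT donor
    # -1) and internal exons start with G (the AG|G acceptor +1); any stop
    # codon this creates is defused at its (unforced) first base
    m <- strsplit(mrna, "")[[1L]]
    forced <- unlist(lapply(bounds, function(b) c(b, b + 1L)))  # 1-based
    for (fp in forced) {
      m[fp] <- "G"
      codon_i <- (fp - 1L - 30L) %/% 3L
      if (fp > 30L && fp - 1L < 30L + 3L * n_codons) {
        cs <- 30L + 3L * codon_i
        cod <- paste(m[(cs + 1L):(cs + 3L)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) m[cs + 1L] <- "C"
      }
    }
    mrna <- paste(m, collapse = "")
    bp_dists <- sample(24:32, 4L, replace = TRUE)
    roles <- c("mini_acceptor", "cassette", "deep_acceptor", "cassette_motif")
    introns <- vapply(seq_len(4L), function(k)
      build_intron(INTRON_LEN[k], roles[k], bp_dists[k]), "")
    flank <- 100L
    contig <- paste0(rand_dna(flank),
                     substr(mrna, 1L, bounds[1L]), introns[1L],
                     substr(mrna, bounds[1L] + 1L, bounds[2L]), introns[2L],
                     substr(mrna, bounds[2L] + 1L, bounds[3L]), introns[3L],
                     substr(mrna, bounds[3L] + 1L, bounds[4L]), introns[4L],
                     substr(mrna, bounds[4L] + 1L, mlen), rand_dna(flank))
    # exon genomic intervals
    ex_starts <- integer(5L); ex_ends <- integer(5L)
    pos <- flank
    for (k in 1:5) {
      ex_starts[k] <- pos; pos <- pos + exon_mlens[k]; ex_ends[k] <- pos
      if (k < 5L) pos <- pos + INTRON_LEN[k]
    }
    exm <- cbind(ex_starts, ex_ends)
    # CDS genomic: mRNA offsets 30 .. 30+3*n_codons
    m2g <- function(off) {  # mRNA offset (0-based) -> genomic
      k <- findInterval(off, c(0L, cumsum(exon_mlens)), rightmost.closed = FALSE)
      ex_starts[k] + off - c(0L, cumsum(exon_mlens))[k]
    }
    cds_start_g <- m2g(30L)
    cds_end_off <- 30L + 3L * n_codons      # half-open mRNA end of CDS
    cds_end_g <- m2g(cds_end_off - 1L) + 1L
    transcripts[[tid]] <- transcript_model(tid, gid, gid, "+", exm,
                                           cds_start_g, cds_end_g)
    istarts <- ex_ends[1:4]
    for (k in 1:4) {
      bp_rows[[length(bp_rows) + 1L]] <- data.table(
        chrom = gid, pos = istarts[k] + INTRON_LEN[k] - bp_dists[k],
        source = "known", intron_idx = k)
    }
    feats[[gid]] <- list(
      intron_starts = istarts, intron_lens = INTRON_LEN,
      bp_dists = bp_dists,
      cassette = list(intron = 2L, acc = istarts[2L] + PE_ACC,
                      don = istarts[2L] + PE_DON),
      cassette_motif = list(intron = 4L, acc = istarts[4L] + PE_ACC,
                            don = istarts[4L] + PE_DON,
                            sil = istarts[4L] + SIL_OFF,
                            enh = istarts[4L] + ENH_OFF),
      deep_acc = istarts[3L] + DEEP_ACC,
      mini_acc = istarts[1L] + INTRON_LEN[1L] - MINI_ACC_FROM_END)
    seqs[gid] <- contig
  }
  motif_sets <- make_motif_sets(seed)
  structure(list(sequences = seqs, transcripts = transcripts,
                 bp_annotation = rbindlist(bp_rows),
                 motif_sets = motif_sets, features = feats,
                 config = config, seed = seed),
            class = "sim_genome")
}

make_motif_sets <- function(seed) {
  set.seed(seed + 104729L)
  b <- c("A", "C", "G", "T")
  rand_hex <- function(n) replicate(n, paste(sample(b, 6L, TRUE), collapse = ""))
  forbidden <- c(ENHANCER_NEARMISS, SILENCER_BROKEN)
  n_t <- function(h) lengths(regmatches(h, gregexpr("T", h)))
  pick <- function(n, include) {
    out <- include
    while (length(out) < n) {
      h <- rand_hex(1L)
      if (n_t(h) >= 2L &&
          !(h %in% c(out, forbidden, ENHANCER_HEX, SILENCER_HEX)))
        out <- c(out, h)
    }
    out
  }
  list(enhancer = motif_set(pick(20L, ENHANCER_HEX), "enhancer",
                            "synthetic_enhancers"),
       silencer = motif_set(pick(20L, SILENCER_HEX), "silencer",
                            "synthetic_silencers"))
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d genes, seed %d\n", length(x$sequences), x$seed))
  invisible(x)
}
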