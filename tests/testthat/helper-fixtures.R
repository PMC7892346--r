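library(data.table)

# Two-exon plus-strand toy: exon1 [100,200), intron [200,500), exon2 [500,600)
toy_two_exon <- function(strand = "+") {
  transcript_model("tx1", "geneA", "chr1", strand,
                   rbind(c(100L, 200L), c(500L, 600L)))
}

# Five-exon coding toy on a synthetic contig; mirrors the simulator layout
# at a smaller scale. Exons of 60 nt, introns of 90 nt.
toy_coding <- function() {
  ex <- cbind(seq(0L, by = 150L, length.out = 5L),
              seq(60L, by = 150L, length.out = 5L))
  # spliced CDS length 276 nt (divisible by 3); stop codon at genomic 648-650
  transcript_model("txc", "geneC", "chrC", "+", ex,
                   cds_start = 15L, cds_end = 651L)
}

# mirror-image minus-strand version of a plus-strand transcript: positions
# x map to (span_max + span_min) - 1 - x
mirror_transcript <- function(t) {
  lims <- range(c(t$exons))
  tot <- sum(lims)
  ex <- cbind(tot - t$exons[, "end"], tot - t$exons[, "start"])
  transcript_model(paste0(t$transcript_id, "_m"), t$gene_id, t$chrom,
                   if (t$strand == "+") "-" else "+", ex)
}

mirror_pos <- function(t, pos) sum(range(c(t$exons))) - 1L - pos

# evidence-row constructor
ev_row <- function(kind, junctions = ".", span = ".", var_pos = ".",
                   var_base = ".", base_qual = ".", sample_id = "s1",
                   gene_id = "geneA", read_id = "r1") {
  data.table(sample_id = sample_id, gene_id = gene_id, read_id = read_id,
             kind = kind, junctions = junctions, span = span,
             var_pos = as.character(var_pos), var_base = var_base,
             base_qual = as.character(base_qual))
}

# independent Fisher oracle: enumerate all tables with the observed margins
# via binomial-coefficient products (no dhyper)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }
  probs <- exp(vapply(lo:hi, logp, 0))
  p_obs <- exp(logp(tab[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-applied BH step-up formula (independent of p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# small simulated study shared across tests (built once per test run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 10L)
      g <- generate_genome(cfg, seed = 401L)
      classes <- c("donor_disrupt", "ss_dinucleotide", "acceptor_disrupt",
                   "ppt_disrupt", "bp_disrupt", "cryptic_donor_gain",
                   "cryptic_acceptor_gain", "cryptic_ppt_gain",
                   "enhancer_gain", "silencer_loss")
      inj <- inject_mutations(g, classes, seed = 402L)
      co <- simulate_cohort(inj$genome, inj$ledger, cfg, seed = 403L)
      cache <<- list(cfg = cfg, genome = inj$genome, ledger = inj$ledger,
                     cohort = co)
    }
    cache
  }
})
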