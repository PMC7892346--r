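# Mutation injection: single-base edits implementing each mechanism class,
# recorded in a ground-truth ledger together with the intended splicing
# event. Classes and their intended events:
#
#   donor_disrupt      +3..+6 consensus base lost      -> full intron retention
#   ss_dinucleotide    donor GT broken                  -> full intron retention
#   acceptor_disrupt   intronic +3 pyrimidine lost      -> full exon skipping
#   ppt_disrupt        PPT pyrimidine (+4..+20) lost    -> full exon skipping
#   bp_disrupt         U2-complementary BP residue lost -> partial intron
#                      retention via the planted mini acceptor
#   cryptic_donor_gain weak -1 of the cassette's pre-existing GT donor
#                      strengthened (GC->GT conversion available via
#                      mechanism = "gc_to_gt")          -> pseudoexon
#   cryptic_acceptor_gain  weak +1 of the deep AG strengthened
#                                                       -> partial retention
#   cryptic_ppt_gain   purine upstream of the deep AG -> pyrimidine
#                                                       -> partial retention
#   enhancer_gain      near-miss hexamer completed      -> pseudoexon
#   silencer_loss      planted silencer hexamer broken  -> pseudoexon
#   neutral            deep intronic edit far from any feature -> no event

base_at <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 1L)

other_base <- function(b, prefer) {
  if (prefer != b) prefer else setdiff(c("A", "C", "G", "T"), b)[1L]
}

#' Inject ground-truth mutations into a synthetic genome
#'
#' One mutation per gene (genes assigned round-robin), each carried by a
#' distinct cancer sample.
#'
#' @param genome A `sim_genome`.
#' @param classes Character vector of mechanism classes (one mutation
#'   each); see `MUTATION_CLASSES`.
#' @param seed Integer seed.
#' @param mechanism For `cryptic_donor_gain`: `"pre_existing"` (default;
#'   the cassette donor GT pre-exists and the variant strengthens its -1
#'   context) or `"gc_to_gt"` (the cassette donor is GC in reference and
#'   the variant converts it to GT; such variants lie outside the mature
#'   pseudoexon and are not allele-verifiable from spliced reads).
#' @return List `variants` (data.table), `ledger` (data.table of class
#'   truth rows), and `genome` (with `gc_to_gt` cassettes rewritten when
#'   requested).
#' @export
inject_mutations <- function(genome, classes, seed = 1L,
                             mechanism = "pre_existing") {
  stopifnot(all(classes %in% MUTATION_CLASSES))
  set.seed(seed + 15485863L)
  cfg <- genome$config
  gids <- names(genome$sequences)
  n_cancer <- cfg$n_cancer_samples
  stopifnot(length(classes) <= n_cancer)
  carrier <- sample(sprintf("C%04d", seq_len(n_cancer)), length(classes))
  rows <- list(); vrows <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    gid <- gids[((i - 1L) %% length(gids)) + 1L]
    ft <- genome$features[[gid]]
    seqs <- genome$sequences[[gid]]
    is1 <- ft$intron_starts[1L]; L1 <- ft$intron_lens[1L]
    acc1 <- is1 + L1                       # authentic acceptor of intron 1
    pos <- NA_integer_; alt <- NA_character_
    intron <- 1L; event <- NA_character_
    cryp_don <- NA_integer_; cryp_acc <- NA_integer_
    if (cl == "donor_disrupt") {
      cons <- c(`3` = "A", `4` = "A", `5` = "G", `6` = "T")
      hit <- NA_integer_
      for (k in 1:4) {
        cand <- which(vapply(3:6, function(p)
          base_at(seqs, ft$intron_starts[k] + p - 1L), "") == cons)
        if (length(cand)) { hit <- k; off <- sample(rep(cand, 2L), 1L); break }
      }
      if (is.na(hit)) { warning("no consensus donor base for ", gid); next }
      intron <- hit
      pos <- ft$intron_starts[hit] + (3:6)[off] - 1L
      alt <- other_base(base_at(seqs, pos), "C")
      event <- "full_intron_retention"
    } else if (cl == "ss_dinucleotide") {
      pos <- is1 + sample(0:1, 1L)          # the G or T of the donor GT
      alt <- other_base(base_at(seqs, pos), "A")
      event <- "full_intron_retention"
    } else if (cl == "acceptor_disrupt") {
      pos <- acc1 - 3L                      # intronic +3 from the acceptor
      alt <- "G"
      event <- "full_exon_skipping"
    } else if (cl == "ppt_disrupt") {
      offs <- (acc1 - 20L):(acc1 - 4L)
      pyr <- offs[vapply(offs, function(p) base_at(seqs, p), "") %in% c("C", "T")]
      pos <- sample(rep(pyr, 2L), 1L)
      alt <- "G"
      event <- "full_exon_skipping"
    } else if (cl == "bp_disrupt") {
      bp <- acc1 - ft$bp_dists[1L]
      rel <- sample(c(-5L, -4L, -3L, -2L, -1L, 1L, 2L, 3L), 1L)
      pos <- bp + rel
      # the window is U2-complementary by construction; break the pairing
      alt <- switch(base_at(seqs, pos), A = "G", C = "A", G = "C", T = "G")
      event <- "partial_intron_retention"
      cryp_acc <- ft$mini_acc
    } else if (cl == "cryptic_donor_gain") {
      intron <- 2L
      if (identical(mechanism, "gc_to_gt")) {
        # rewrite this cassette donor to GC in the reference
        don_off <- ft$cassette$don
        substr(seqs, don_off + 2L, don_off + 2L) <- "C"
        genome$sequences[[gid]] <- seqs
        pos <- don_off + 1L; alt <- "T"
      } else {
        pos <- ft$cassette$don - 1L          # weak -1 (A) -> G
        alt <- "G"
      }
      event <- "pseudoexon_activation"
      cryp_don <- ft$cassette$don; cryp_acc <- ft$cassette$acc
    } else if (cl == "cryptic_acceptor_gain") {
      intron <- 3L
      pos <- ft$deep_acc                     # weak +1 (A) -> G
      alt <- "G"
      event <- "partial_intron_retention"
      cryp_acc <- ft$deep_acc
    } else if (cl == "cryptic_ppt_gain") {
      intron <- 3L
      offs <- (ft$deep_acc - 18L):(ft$deep_acc - 4L)
      pur <- offs[vapply(offs, function(p) base_at(seqs, p), "") %in% c("A", "G")]
      pos <- sample(rep(pur, 2L), 1L)
      alt <- "T"
      event <- "partial_intron_retention"
      cryp_acc <- ft$deep_acc
    } else if (cl == "enhancer_gain") {
      intron <- 4L
      pos <- ft$cassette_motif$enh + 2L      # near-miss position 3: T -> A
      alt <- "A"
      event <- "pseudoexon_activation"
      cryp_don <- ft$cassette_motif$don; cryp_acc <- ft$cassette_motif$acc
    } else if (cl == "silencer_loss") {
      intron <- 4L
      pos <- ft$cassette_motif$sil + 3L      # silencer position 4: G -> C
      alt <- "C"
      event <- "pseudoexon_activation"
      cryp_don <- ft$cassette_motif$don; cryp_acc <- ft$cassette_motif$acc
    } else if (cl == "neutral") {
      pos <- is1 + sample(60:180, 1L)
      alt <- other_base(base_at(seqs, pos), "T")
      event <- NA_character_
    }
    ref <- base_at(genome$sequences[[gid]], pos)
    stopifnot(ref != alt)
    vid <- sprintf("v%03d", i)
    r_int <- if (cl == "neutral") NA_real_
    else runif(1L, cfg$effect_range[1L], cfg$effect_range[2L])
    rows[[length(rows) + 1L]] <- data.table(
      variant_id = vid, gene_id = gid, sample_id = carrier[i], chrom = gid,
      pos = pos, ref = ref, alt = alt, class = cl, intended_event = event,
      intron_idx = intron, cryptic_donor = cryp_don,
      cryptic_acceptor = cryp_acc, intended_ratio = r_int,
      allele_linkage = cfg$fidelity, ptc_expectation = NA_character_)
    vrows[[length(vrows) + 1L]] <- data.table(
      variant_id = vid, chrom = gid, pos = pos, ref = ref, alt = alt,
      kind = "SNV", sample_id = carrier[i],
      caller_count = 3L, db_maf = NA_real_, cosmic_recurrence = 0L)
  }
  ledger <- rbindlist(rows)
  # fill the PTC expectation by scanning the intended aberrant transcript
  for (j in seq_len(nrow(ledger))) {
    ev <- intended_event_object(ledger[j], genome)
    if (is.null(ev)) next
    pc <- ptc_scan(ev, genome$transcripts[[paste0(ledger$gene_id[j], ".t1")]],
                   genome$sequences[[ledger$gene_id[j]]])
    ledger[j, ptc_expectation := pc$nmd_class]
  }
  list(variants = rbindlist(vrows), ledger = ledger, genome = genome)
}

#' Reconstruct the intended splice event of a ledger row
#'
#' @param row One-row `data.table` of the truth ledger.
#' @param genome The `sim_genome`.
#' @return A `splice_event`, or `NULL` for neutral rows.
#' @export
intended_event_object <- function(row, genome) {
  if (is.na(row$intended_event)) return(NULL)
  ev <- list(event_type = row$intended_event, intron_idx = row$intron_idx,
             abnormal_count = NA_integer_)
  if (!is.na(row$cryptic_donor)) ev$cryptic_donor <- row$cryptic_donor
  if (!is.na(row$cryptic_acceptor)) ev$cryptic_acceptor <- row$cryptic_acceptor
  if (row$intended_event == "pseudoexon_activation")
    ev$pseudoexon <- c(row$cryptic_acceptor, row$cryptic_donor)
  if (row$intended_event == "full_exon_skipping")
    ev$skipped_exons <- row$intron_idx + 1L   # the exon downstream of intron k
  structure(ev, class = "splice_event")
}
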