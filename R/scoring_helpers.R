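# Convenience layer tying the splice-code scorers to a genome and a truth
# ledger: training-window extraction, default models, per-class strength
# deltas, and feature construction for the one-class models.

#' Authentic splice-site windows of an annotated genome
#'
#' @param genome `sim_genome` (or list with `sequences` and `transcripts`).
#' @return List `donor` (9-mers), `acceptor` (23-mers).
#' @export
authentic_splice_windows <- function(genome) {
  don <- character(0); acc <- character(0)
  for (t in genome$transcripts) {
    seqs <- genome$sequences[[t$chrom]]
    it <- transcript_introns(t)
    for (k in seq_len(nrow(it))) {
      don <- c(don, splice_site_window(seqs, it$donor_end[k], "donor",
                                       t$strand))
      acc <- c(acc, splice_site_window(seqs, it$acceptor_start[k], "acceptor",
                                       t$strand))
    }
  }
  list(donor = don, acceptor = acc)
}

#' Default splice-strength models trained on a genome's own junctions
#'
#' @param genome `sim_genome`.
#' @return List `donor`, `acceptor` of `splice_strength_model`.
#' @export
default_strength_models <- function(genome) {
  w <- authentic_splice_windows(genome)
  list(donor = train_splice_model(w$donor, "donor"),
       acceptor = train_splice_model(w$acceptor, "acceptor"))
}

#' Branchpoint window sequence (8 nt, BP excluded)
#'
#' @param genome_seq Chromosome sequence.
#' @param bp_pos 0-based BP position.
#' @param strand `"+"` or `"-"`.
#' @param alt Optional substitution `list(pos, alt)` applied before
#'   extraction.
#' @return 8-character window (5 bp upstream + 3 bp downstream of the BP).
#' @export
bp_window_seq <- function(genome_seq, bp_pos, strand = "+", alt = NULL) {
  s <- as.character(genome_seq)
  if (!is.null(alt)) substr(s, alt$pos + 1L, alt$pos + 1L) <- alt$alt
  up <- substr(s, bp_pos - 4L, bp_pos)        # bp-5 .. bp-1 (0-based)
  dn <- substr(s, bp_pos + 2L, bp_pos + 4L)   # bp+1 .. bp+3
  w <- paste0(up, dn)
  if (strand == "-") w <- revcomp(w)
  w
}

#' Class-appropriate splice-code alteration of each ledger mutation
#'
#' Donor-side classes are scored by the donor model delta at the relevant
#' (authentic or cryptic) donor; acceptor/PPT classes by the acceptor model
#' delta; branchpoint disruptions by the U2 duplex energy change. Motif
#' classes (enhancer gain / silencer loss) are scored by [motif_scan()]
#' gain/loss indicators.
#'
#' @param genome `sim_genome` (post-injection).
#' @param ledger Truth ledger.
#' @param models Optional [default_strength_models()] result.
#' @return `data.table(variant_id, class, metric, value)`; `metric` is
#'   `delta_donor`, `delta_acceptor`, `ddg_u2`, `motif_gain` or
#'   `motif_loss`.
#' @export
score_truth_classes <- function(genome, ledger,
                                models = default_strength_models(genome)) {
  out <- list()
  for (j in seq_len(nrow(ledger))) {
    row <- ledger[j]
    seqs <- genome$sequences[[row$chrom]]
    t <- genome$transcripts[[paste0(row$gene_id, ".t1")]]
    it <- transcript_introns(t)
    v <- list(pos = row$pos, ref = row$ref, alt = row$alt)
    cl <- row$class
    metric <- NA_character_; value <- NA_real_
    if (cl %in% c("donor_disrupt", "ss_dinucleotide")) {
      d <- strength_delta(v, it$donor_end[row$intron_idx], seqs,
                          models$donor, t$strand)
      metric <- "delta_donor"; value <- d$delta
    } else if (cl %in% c("acceptor_disrupt", "ppt_disrupt")) {
      d <- strength_delta(v, it$acceptor_start[row$intron_idx], seqs,
                          models$acceptor, t$strand)
      metric <- "delta_acceptor"; value <- d$delta
    } else if (cl == "cryptic_donor_gain") {
      d <- strength_delta(v, row$cryptic_donor, seqs, models$donor, t$strand)
      metric <- "delta_donor"; value <- d$delta
    } else if (cl %in% c("cryptic_acceptor_gain", "cryptic_ppt_gain")) {
      d <- strength_delta(v, row$cryptic_acceptor, seqs, models$acceptor,
                          t$strand)
      metric <- "delta_acceptor"; value <- d$delta
    } else if (cl == "bp_disrupt") {
      bps <- genome$bp_annotation[chrom == row$chrom &
                                    intron_idx == row$intron_idx]
      wt <- bp_window_seq(seqs, bps$pos[1L], t$strand)
      mu <- bp_window_seq(seqs, bps$pos[1L], t$strand,
                          alt = list(pos = row$pos, alt = row$alt))
      metric <- "ddg_u2"; value <- u2_delta_energy(wt, mu)$ddg
    } else if (cl %in% c("enhancer_gain", "silencer_loss")) {
      set <- if (cl == "enhancer_gain") genome$motif_sets$enhancer
      else genome$motif_sets$silencer
      ms <- motif_scan(flank_11mer(seqs, row$pos),
                       flank_11mer(seqs, row$pos, row$alt), set)
      if (cl == "enhancer_gain") {
        metric <- "motif_gain"; value <- as.numeric(ms$mut_hit && !ms$wt_hit)
      } else {
        metric <- "motif_loss"; value <- as.numeric(ms$wt_hit && !ms$mut_hit)
      }
    }
    out[[j]] <- data.table(variant_id = row$variant_id, class = cl,
                           metric = metric, value = value)
  }
  rbindlist(out)
}

#' One-class model features for a set of variants at model-class positions
#'
#' @param genome `sim_genome`.
#' @param variants `data.table(chrom, pos, ref, alt)` (0-based positions at
#'   donor +3..+6, donor -2..-1, or acceptor +3 sites).
#' @param models [default_strength_models()] result.
#' @return `data.table` with `model_class`, `f1`, `f2` appended (rows at
#'   ineligible positions are dropped).
#' @export
variant_features <- function(genome, variants,
                             models = default_strength_models(genome)) {
  out <- list()
  for (j in seq_len(nrow(variants))) {
    v <- variants[j]
    t <- select_longest_isoform(
      Filter(function(x) x$chrom == v$chrom, genome$transcripts))
    loc <- classify_variant_location(v$pos, t)
    mc <- feature_model_class(loc)
    if (is.na(mc) || is.null(loc$intron_idx)) next
    it <- transcript_introns(t)
    k <- loc$intron_idx
    ft <- tryCatch(
      make_features(list(pos = v$pos, ref = v$ref, alt = v$alt), loc,
                    it$donor_end[k], it$acceptor_start[k],
                    genome$sequences[[v$chrom]], models$donor,
                    models$acceptor, t$strand),
      error = function(e) NULL)
    if (is.null(ft)) next
    row <- copy(v)
    row[, `:=`(model_class = ft$model_class, f1 = ft$f1, f2 = ft$f2)]
    out[[length(out) + 1L]] <- row
  }
  rbindlist(out, fill = TRUE)
}

#' Random SNVs at one-class model positions (comparator universe)
#'
#' Uniformly draws introns and positions of the requested model class and
#' random alternate alleles: the training universe of the random-mutation
#' comparator model.
#'
#' @param genome `sim_genome`.
#' @param n Number of SNVs.
#' @param model_class `"donor_intronic"`, `"donor_exonic"` or
#'   `"acceptor_intronic"`.
#' @param seed RNG seed.
#' @return `data.table(chrom, pos, ref, alt)`.
#' @export
random_site_variants <- function(genome, n, model_class = "donor_intronic",
                                 seed = 1L) {
  set.seed(seed)
  gids <- names(genome$sequences)
  rows <- list()
  for (i in seq_len(n)) {
    gid <- sample(gids, 1L)
    t <- genome$transcripts[[paste0(gid, ".t1")]]
    it <- transcript_introns(t)
    k <- sample(nrow(it), 1L)
    pos <- switch(model_class,
                  donor_intronic = it$donor_end[k] + sample(2:5, 1L),
                  donor_exonic = it$donor_end[k] - sample(1:2, 1L),
                  acceptor_intronic = it$acceptor_start[k] - 3L,
                  stop("unknown model class"))
    ref <- substr(genome$sequences[[gid]], pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    rows[[i]] <- data.table(chrom = gid, pos = pos, ref = ref, alt = alt)
  }
  rbindlist(rows)
}
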