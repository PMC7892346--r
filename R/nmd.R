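# PTC and NMD analysis: reconstruct the aberrant mature mRNA implied by a
# splice event, translate from the annotated start codon, and classify any
# premature termination codon by the canonical junction rule: PTCs within
# the first 250 nt of the CDS, or from 55 nt upstream of the last exon-exon
# junction to the end of the last exon, escape NMD (insensitive); all other
# PTCs elicit NMD (sensitive).
#
# The CDS interval of a transcript model includes the stop codon; PTC
# positions are measured in CDS coordinates of the aberrant transcript
# (the frame in which the PTC exists).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Exon chain of the aberrant transcript implied by a splice event
#'
#' @param event A `splice_event` (non-combinatorial).
#' @param t `transcript_model`.
#' @return Matrix of exon intervals (0-based half-open, transcript order).
#' @export
aberrant_exons <- function(event, t) {
  ex <- t$exons
  n <- nrow(ex)
  k <- event$intron_idx
  type <- event$event_type
  if (type == "full_intron_retention") {
    stopifnot(!is.na(k), k < n)
    merged <- c(min(ex[k, "start"], ex[k + 1L, "start"]),
                max(ex[k, "end"], ex[k + 1L, "end"]))
    ex <- rbind(ex[seq_len(k - 1L), , drop = FALSE], merged,
                ex[seq_len(n)[-seq_len(k + 1L)], , drop = FALSE])
  } else if (type == "partial_intron_retention") {
    if (!is.null(event$cryptic_acceptor)) {
      c0 <- event$cryptic_acceptor
      if (t$strand == "+") ex[k + 1L, "start"] <- c0 else ex[k + 1L, "end"] <- c0
    } else if (!is.null(event$cryptic_donor)) {
      c0 <- event$cryptic_donor
      if (t$strand == "+") ex[k, "end"] <- c0 else ex[k, "start"] <- c0
    } else stop("partial retention event lacks a cryptic site")
  } else if (type == "pseudoexon_activation") {
    pe <- event$pseudoexon
    ex <- rbind(ex[seq_len(k), , drop = FALSE], pe,
                ex[seq_len(n)[-seq_len(k)], , drop = FALSE])
  } else if (type == "full_exon_skipping") {
    stopifnot(length(event$skipped_exons) >= 1L)
    ex <- ex[-event$skipped_exons, , drop = FALSE]
  } else if (type == "partial_exon_skipping") {
    p <- event$truncation
    j <- which(p > ex[, "start"] & p < ex[, "end"])
    stopifnot(length(j) == 1L)
    a <- event$junction[1L]; b <- event$junction[2L]
    if (p == a) ex[j, "end"] <- p
    else if (p == b) ex[j, "start"] <- p
    else stop("truncation position not an end of the novel junction")
  } else stop("cannot build an exon chain for event type '", type, "'")
  m <- matrix(as.integer(ex), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  m
}

spliced_sequence <- function(chain, genome_seq, strand) {
  genome_seq <- as.character(genome_seq)
  parts <- vapply(seq_len(nrow(chain)), function(i)
    substr(genome_seq, chain[i, "start"] + 1L, chain[i, "end"]), "")
  if (strand == "-") parts <- vapply(parts, revcomp, "")
  paste(parts, collapse = "")
}

# transcript coordinate (0-based) of a genomic position within a chain
map_to_tpos <- function(chain, strand, gpos) {
  off <- 0L
  for (i in seq_len(nrow(chain))) {
    s <- chain[i, "start"]; e <- chain[i, "end"]
    if (gpos >= s && gpos < e) {
      return(unname(off + if (strand == "+") gpos - s else e - 1L - gpos))
    }
    off <- off + (e - s)
  }
  NA_integer_
}

#' Scan an aberrant transcript for a premature termination codon
#'
#' For variants inducing several forms of the same event type, the form
#' with the highest abnormal-read ratio is analysed (pass that form).
#' Combinatorial events are analysed per sub-event; when sub-events
#' disagree on PTC presence or NMD class the call is excluded as
#' inconsistent.
#'
#' @param event A `splice_event`.
#' @param t `transcript_model` (CDS required; non-coding returns class
#'   `"none"`).
#' @param genome_seq Chromosome sequence.
#' @param nmd_rule `c(250, 55)` insensitivity bounds.
#' @return List of class `ptc_call`: `nmd_class` (`sensitive`,
#'   `insensitive`, `none`, `excluded_inconsistent`), `ptc_cds_position`
#'   (1-based nt of the stop codon's first base in the aberrant CDS, or
#'   `NA`), `last_junction_cds` and `cds_length` diagnostics.
#' @export
ptc_scan <- function(event, t, genome_seq, nmd_rule = c(250L, 55L)) {
  none <- function() structure(list(nmd_class = "none",
                                    ptc_cds_position = NA_integer_,
                                    last_junction_cds = NA_integer_,
                                    cds_length = NA_integer_),
                               class = "ptc_call")
  if (is.na(t$cds_start)) return(none())
  if (identical(event$event_type, "combinatorial")) {
    subs <- lapply(event$sub_events, ptc_scan, t = t,
                   genome_seq = genome_seq, nmd_rule = nmd_rule)
    cls <- vapply(subs, `[[`, "", "nmd_class")
    if (length(unique(cls)) > 1L)
      return(structure(list(nmd_class = "excluded_inconsistent",
                            ptc_cds_position = NA_integer_,
                            last_junction_cds = NA_integer_,
                            cds_length = NA_integer_), class = "ptc_call"))
    return(subs[[1L]])
  }
  chain <- aberrant_exons(event, t)
  # UTR-only events do not enter the PTC analysis
  touched <- event_footprint(event, t)
  if (!is.null(touched) &&
      (touched[2L] <= t$cds_start || touched[1L] >= t$cds_end)) return(none())
  seqs <- spliced_sequence(chain, genome_seq, t$strand)
  start_g <- if (t$strand == "+") t$cds_start else t$cds_end - 1L
  stop_g <- if (t$strand == "+") t$cds_end - 3L else t$cds_start + 2L
  cds_t0 <- map_to_tpos(chain, t$strand, start_g)
  if (is.na(cds_t0)) return(none())  # start codon removed by the event
  stop_t <- map_to_tpos(chain, t$strand, stop_g)
  # translate from the start codon; first in-frame stop
  first_stop <- NA_integer_
  i <- cds_t0
  while (i + 3L <= nchar(seqs)) {
    codon <- substr(seqs, i + 1L, i + 3L)
    if (codon %in% STOP_CODONS) { first_stop <- i; break }
    i <- i + 3L
  }
  lens <- chain[, "end"] - chain[, "start"]
  last_junction_t <- if (nrow(chain) > 1L) sum(lens[-nrow(chain)]) else NA_integer_
  lj_cds <- if (is.na(last_junction_t)) NA_integer_ else last_junction_t - cds_t0
  if (is.na(first_stop)) {
    # stop-free to transcript end (annotated stop disrupted, no earlier stop)
    return(structure(list(nmd_class = "none",
                          ptc_cds_position = NA_integer_,
                          last_junction_cds = lj_cds,
                          cds_length = nchar(seqs) - cds_t0),
                     class = "ptc_call"))
  }
  is_annotated_stop <- !is.na(stop_t) && first_stop == stop_t
  if (is_annotated_stop) {
    return(structure(list(nmd_class = "none",
                          ptc_cds_position = NA_integer_,
                          last_junction_cds = lj_cds,
                          cds_length = first_stop - cds_t0 + 3L),
                     class = "ptc_call"))
  }
  ptc_pos <- first_stop - cds_t0 + 1L  # 1-based nt in aberrant CDS
  cls <- nmd_classify(ptc_pos, lj_cds, nmd_rule)
  structure(list(nmd_class = cls, ptc_cds_position = ptc_pos,
                 last_junction_cds = lj_cds,
                 cds_length = first_stop - cds_t0 + 3L),
            class = "ptc_call")
}

# genomic interval modified by an event (for the UTR-only check)
event_footprint <- function(event, t) {
  it <- transcript_introns(t)
  k <- event$intron_idx
  switch(event$event_type,
         full_intron_retention = c(it$start[k], it$end[k]),
         partial_intron_retention = c(it$start[k], it$end[k]),
         pseudoexon_activation = event$pseudoexon,
         full_exon_skipping = {
           ex <- t$exons[event$skipped_exons, , drop = FALSE]
           c(min(ex[, "start"]), max(ex[, "end"]))
         },
         partial_exon_skipping = sort(event$junction),
         NULL)
}

#' Classify a premature termination codon as NMD-sensitive or -insensitive
#'
#' @param ptc_cds_position 1-based position (nt) of the PTC's first base in
#'   the aberrant CDS.
#' @param last_junction_cds Position (nt from CDS start) of the last
#'   exon-exon junction of the aberrant transcript; `NA` for single-exon
#'   transcripts (classified insensitive: no junction to trigger NMD).
#' @param rule `c(250, 55)`: insensitive within the first `rule[1]` nt or
#'   at/after `last_junction_cds - rule[2]`.
#' @return `"sensitive"` or `"insensitive"`.
#' @export
nmd_classify <- function(ptc_cds_position, last_junction_cds,
                         rule = c(250L, 55L)) {
  stopifnot(ptc_cds_position >= 1L)
  if (is.na(last_junction_cds)) return("insensitive")
  if (ptc_cds_position <= rule[1L]) return("insensitive")
  if (ptc_cds_position >= last_junction_cds - rule[2L]) return("insensitive")
  "sensitive"
}
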