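# Typing of abnormal splicing events from abnormal-read geometry.
#
# The per-event read-counting geometry reconstructs six event classes from
# junction evidence alone:
#   - a single novel junction from an annotated donor into an intron
#     (cryptic acceptor), or from inside an intron to an annotated acceptor
#     (cryptic donor), is partial intron retention;
#   - the complementary pair of novel junctions bracketing an internal
#     interval of one intron is pseudoexon activation;
#   - a junction joining two annotated boundaries that skips whole annotated
#     exons is full exon skipping;
#   - a junction truncating an annotated exon is partial exon skipping;
#   - unspliced retention evidence with no novel junction is full intron
#     retention;
#   - two or more distinct abnormal geometries at one locus are combinatorial.

MIN_SEGMENT_LEN <- 10L  # pseudoexons / retained segments below this are artifacts

#' Type an abnormal splicing event from its supporting reads
#'
#' @param abn_reads Abnormal evidence rows (as classified by
#'   [classify_reads()]) for one gene and sample.
#' @param t `transcript_model` of the gene.
#' @param known Optional [known_junctions()] table.
#' @return List of `splice_event` objects (one per distinct geometry; a
#'   wrapping `combinatorial` event is appended when there are several).
#'   Each event carries `event_type`, `intron_idx`, optional
#'   `cryptic_donor` / `cryptic_acceptor` genomic positions, optional
#'   `pseudoexon` interval, and `abnormal_count`.
#' @export
type_event <- function(abn_reads, t, known = known_junctions(t)) {
  abn_reads <- as.data.table(abn_reads)
  if (!nrow(abn_reads)) stop("no abnormal reads supplied")
  if (!"intron_idx" %in% names(abn_reads))
    abn_reads <- classify_reads(abn_reads, t, known)[class == "abnormal"]
  it <- transcript_introns(t)
  ex <- t$exons
  donors <- it$donor_end; acceptors <- it$acceptor_start
  kk <- paste(known$jx_start, known$jx_end)

  # collect distinct novel junctions with read support
  nvl <- list()
  for (i in seq_len(nrow(abn_reads))) {
    if (abn_reads$kind[i] != "junction") next
    jm <- parse_junctions(abn_reads$junctions[i])
    novel <- jm[!(paste(jm[, 1L], jm[, 2L]) %in% kk), , drop = FALSE]
    for (r in seq_len(nrow(novel)))
      nvl[[length(nvl) + 1L]] <- c(novel[r, ], i)
  }
  ret_idx <- which(abn_reads$kind == "unspliced_span")

  jx <- if (length(nvl)) {
    m <- do.call(rbind, nvl)
    dt <- data.table(a = m[, 1L], b = m[, 2L], read = m[, 3L])
    dt[, .(n_reads = .N, reads = list(unique(read))), by = .(a, b)]
  } else data.table(a = integer(), b = integer(), n_reads = integer(),
                    reads = list())

  in_intron <- function(p) {
    k <- which(p > it$start & p < it$end)
    if (length(k)) k[1L] else NA_integer_
  }
  in_exon <- function(p) {
    k <- which(p > ex[, "start"] & p < ex[, "end"])
    if (length(k)) k[1L] else NA_integer_
  }

  geoms <- list()
  if (nrow(jx)) {
    plus <- t$strand == "+"
    for (g in seq_len(nrow(jx))) {
      a <- jx$a[g]; b <- jx$b[g]; nr <- jx$n_reads[g]
      # genomic left end a = junction donor_end on +, acceptor_start on -
      don <- if (plus) a else b
      acc <- if (plus) b else a
      don_annot <- don %in% donors
      acc_annot <- acc %in% acceptors
      ki_don <- in_intron(if (plus) b else a)  # cryptic end inside intron?
      geom <- NULL
      if (don_annot && acc_annot) {
        # both annotated boundaries but novel pairing: exon skipping
        skipped <- which(ex[, "start"] > min(a, b) & ex[, "end"] < max(a, b))
        geom <- list(event_type = "full_exon_skipping",
                     skipped_exons = skipped,
                     intron_idx = {
                       k <- which(it$start >= a & it$end <= b)
                       if (length(k)) k[1L] else NA_integer_
                     })
      } else if (don_annot && !acc_annot) {
        p <- acc
        if (!is.na(in_intron(p))) {
          geom <- list(event_type = "partial_intron_retention",
                       cryptic_acceptor = p, intron_idx = in_intron(p))
        } else if (!is.na(in_exon(p))) {
          geom <- list(event_type = "partial_exon_skipping",
                       truncation = p, intron_idx = NA_integer_)
        }
      } else if (!don_annot && acc_annot) {
        p <- don
        if (!is.na(in_intron(p))) {
          geom <- list(event_type = "partial_intron_retention",
                       cryptic_donor = p, intron_idx = in_intron(p))
        } else if (!is.na(in_exon(p))) {
          geom <- list(event_type = "partial_exon_skipping",
                       truncation = p, intron_idx = NA_integer_)
        }
      } else {
        # both ends novel, inside one intron: half of a pseudoexon
        ki <- in_intron(don)
        if (!is.na(ki) && identical(ki, in_intron(acc)))
          geom <- list(event_type = "pseudoexon_half", cryptic_donor = don,
                       cryptic_acceptor = acc, intron_idx = ki)
      }
      if (is.null(geom)) {
        warning("novel junction ", a, "-", b,
                " matches no event geometry; excluded")
        next
      }
      geom$abnormal_count <- nr
      geom$junction <- c(a, b)
      geoms[[length(geoms) + 1L]] <- geom
    }
  }

  # pair partial-retention geometries into pseudoexons: an annotated-donor ->
  # cryptic-acceptor junction plus a cryptic-donor -> annotated-acceptor
  # junction in the same intron, cryptic acceptor 5' of cryptic donor
  events <- list()
  used <- rep(FALSE, length(geoms))
  for (i in seq_along(geoms)) {
    gi <- geoms[[i]]
    if (used[i] || gi$event_type != "partial_intron_retention" ||
        is.null(gi$cryptic_acceptor)) next
    for (j in seq_along(geoms)) {
      gj <- geoms[[j]]
      if (used[j] || i == j || gj$event_type != "partial_intron_retention" ||
          is.null(gj$cryptic_donor) || gj$intron_idx != gi$intron_idx) next
      acc <- gi$cryptic_acceptor; don <- gj$cryptic_donor
      pe <- if (t$strand == "+") c(acc, don) else c(don, acc)
      if (pe[2L] - pe[1L] >= MIN_SEGMENT_LEN) {
        events[[length(events) + 1L]] <- list(
          event_type = "pseudoexon_activation", intron_idx = gi$intron_idx,
          cryptic_acceptor = acc, cryptic_donor = don,
          pseudoexon = pe,
          abnormal_count = max(gi$abnormal_count, gj$abnormal_count),
          one_sided = FALSE)
        used[c(i, j)] <- TRUE
        break
      }
    }
  }
  for (i in seq_along(geoms)) {
    if (used[i]) next
    gi <- geoms[[i]]
    if (gi$event_type == "pseudoexon_half") {
      # both junctions carried on single reads
      pe <- sort(c(gi$cryptic_donor, gi$cryptic_acceptor))
      gi$event_type <- "pseudoexon_activation"
      gi$pseudoexon <- pe
      gi$one_sided <- TRUE   # flagged: only intra-intron pairing observed
    }
    events[[length(events) + 1L]] <- gi
  }

  if (length(ret_idx) && length(events) == 0L) {
    loci <- unique(abn_reads$intron_idx[ret_idx])
    loci <- loci[!is.na(loci)]
    for (k in loci) {
      events[[length(events) + 1L]] <- list(
        event_type = "full_intron_retention", intron_idx = k,
        abnormal_count = sum(abn_reads$kind[ret_idx] == "unspliced_span" &
                               abn_reads$intron_idx[ret_idx] == k))
    }
  } else if (length(ret_idx)) {
    # retention evidence alongside novel junctions contributes to the
    # combinatorial wrap-up below but not a separate full-retention call
    events[[length(events) + 1L]] <- list(
      event_type = "full_intron_retention",
      intron_idx = unique(abn_reads$intron_idx[ret_idx])[1L],
      abnormal_count = length(ret_idx))
  }

  events <- lapply(events, function(e) structure(e, class = "splice_event"))
  if (length(events) > 1L) {
    comb <- structure(list(event_type = "combinatorial",
                           sub_events = events,
                           intron_idx = events[[1L]]$intron_idx,
                           abnormal_count = sum(vapply(events, `[[`, 0L,
                                                       "abnormal_count"))),
                      class = "splice_event")
    events <- c(events, list(comb))
  }
  events
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s (intron %s, %d abnormal reads)\n",
              x$event_type, x$intron_idx, x$abnormal_count))
  invisible(x)
}

#' Audit cryptic splice-site dinucleotides against the reference
#'
#' Cryptic donors must begin GT in the reference, or become GT through the
#' variant (GC-to-GT conversion); cryptic acceptors must be preceded by a
#' reference AG. An audit flag is raised when neither holds.
#'
#' @param event A `splice_event` with cryptic site positions.
#' @param genome_seq Reference sequence of the chromosome (character or
#'   `DNAString`). Plus-strand genes assumed for the dinucleotide read-out;
#'   minus-strand windows are reverse-complemented.
#' @param strand `"+"` or `"-"`.
#' @param variant Optional list `pos` (0-based), `ref`, `alt`.
#' @return The event with `donor_origin` (`"pre_existing"`,
#'   `"created_by_variant"`, or `NA`), `acceptor_ag` (logical) and
#'   `audit_flag` fields added.
#' @export
locate_cryptic_sites <- function(event, genome_seq, strand = "+",
                                 variant = NULL) {
  genome_seq <- as.character(genome_seq)
  sub0 <- function(s, e) {  # 0-based half-open extraction, strand-aware
    x <- substr(genome_seq, s + 1L, e)
    if (strand == "-") x <- revcomp(x)
    x
  }
  event$audit_flag <- FALSE
  if (!is.null(event$cryptic_donor)) {
    d <- event$cryptic_donor
    din <- if (strand == "+") sub0(d, d + 2L) else sub0(d - 2L, d)
    if (din == "GT") {
      event$donor_origin <- "pre_existing"
    } else {
      created <- FALSE
      if (!is.null(variant) && din == "GC") {
        # does the variant convert the C (second intronic base) to T?
        cpos <- if (strand == "+") d + 1L else d - 2L
        created <- variant$pos == cpos &&
          ((strand == "+" && variant$ref == "C" && variant$alt == "T") ||
             (strand == "-" && variant$ref == "G" && variant$alt == "A"))
      }
      if (created) {
        event$donor_origin <- "created_by_variant"
      } else {
        event$donor_origin <- NA_character_
        event$audit_flag <- TRUE
      }
    }
  }
  if (!is.null(event$cryptic_acceptor)) {
    a <- event$cryptic_acceptor
    din <- if (strand == "+") sub0(a - 2L, a) else sub0(a, a + 2L)
    event$acceptor_ag <- din == "AG"
    if (!event$acceptor_ag) event$audit_flag <- TRUE
  }
  event
}

#' Pseudoexon interval and length
#'
#' @param event A `pseudoexon_activation` event.
#' @return List `interval` (0-based half-open genomic) and `length`.
#' @export
pseudoexon_bounds <- function(event) {
  if (!identical(event$event_type, "pseudoexon_activation"))
    stop("not a pseudoexon event")
  pe <- event$pseudoexon
  if (is.null(pe) || pe[2L] <= pe[1L])
    stop("cryptic donor not downstream of cryptic acceptor")
  list(interval = pe, length = pe[2L] - pe[1L])
}

#' Reverse complement of a DNA string (helper)
#' @param x Character scalar over ACGTN.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}
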