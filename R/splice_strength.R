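# Splice-site strength scoring. The default scorer is a smoothed position
# log-odds model trained on a supplied set of authentic junction windows
# (donor: 3 exonic + 6 intronic bases = 9-mer; acceptor: 20 intronic + 3
# exonic = 23-mer); externally supplied per-position probability tables
# (e.g. exported maximum-entropy marginals) load through the same
# interface. Scores are in log2 odds against a uniform background, so 0 is
# "no information" and higher means a stronger site.

DONOR_EXONIC <- 3L; DONOR_INTRONIC <- 6L
ACCEPTOR_INTRONIC <- 20L; ACCEPTOR_EXONIC <- 3L

#' Window length of a splice-strength model side
#' @param side `"donor"` or `"acceptor"`.
#' @return Integer window length (9 or 23).
#' @export
splice_window_length <- function(side) {
  switch(side, donor = DONOR_EXONIC + DONOR_INTRONIC,
         acceptor = ACCEPTOR_INTRONIC + ACCEPTOR_EXONIC,
         stop("side must be 'donor' or 'acceptor'"))
}

new_strength_model <- function(probs, side, provenance) {
  L <- splice_window_length(side)
  stopifnot(identical(dim(probs), c(4L, L)))
  probs <- sweep(probs, 2L, colSums(probs), "/")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(side = side, probs = probs,
                 weights = log2(probs / 0.25), provenance = provenance),
            class = "splice_strength_model")
}

#' @export
print.splice_strength_model <- function(x, ...) {
  cat(sprintf("<splice_strength_model> side=%s L=%d (%s)\n", x$side,
              ncol(x$probs), x$provenance))
  invisible(x)
}

#' Train a position log-odds splice-strength model
#'
#' Per-position base probabilities with add-one smoothing,
#' `p = (count + 1) / (n + 4)`.
#'
#' @param windows Character vector of equal-length ACGT windows (length 9
#'   for donors, 23 for acceptors).
#' @param side `"donor"` or `"acceptor"`.
#' @return A `splice_strength_model`.
#' @export
train_splice_model <- function(windows, side) {
  L <- splice_window_length(side)
  if (!length(windows)) stop("no training windows")
  if (any(nchar(windows) != L)) stop("training windows must be ", L, "-mers")
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  if (any(!mat %in% c("A", "C", "G", "T"))) stop("non-ACGT training window")
  counts <- apply(mat, 2L, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))))
  probs <- (counts + 1) / (nrow(mat) + 4)
  new_strength_model(probs, side, sprintf("trained on %d windows", nrow(mat)))
}

#' Load an externally supplied splice-strength table
#'
#' @param path TSV with columns `pos, A, C, G, T` (per-position
#'   probabilities, one row per window position in order).
#' @param side `"donor"` or `"acceptor"`.
#' @return A `splice_strength_model`.
#' @export
load_splice_model <- function(path, side) {
  tab <- fread(path, sep = "\t")
  stopifnot(all(c("pos", "A", "C", "G", "T") %in% names(tab)))
  tab <- tab[order(pos)]
  probs <- t(as.matrix(tab[, c("A", "C", "G", "T"), with = FALSE]))
  new_strength_model(probs, side, paste("loaded from", basename(path)))
}

#' Score a splice-site window
#'
#' @param window_seq ACGT string matching the model's window length.
#' @param model A `splice_strength_model`.
#' @return Log2-odds score (sum of per-position terms).
#' @export
score_splice_site <- function(window_seq, model) {
  window_seq <- toupper(window_seq)
  L <- ncol(model$probs)
  if (nchar(window_seq) != L)
    stop("window length ", nchar(window_seq), " != model length ", L)
  b <- strsplit(window_seq, "")[[1L]]
  if (any(!b %in% c("A", "C", "G", "T"))) stop("non-ACGT base in window")
  idx <- match(b, rownames(model$weights)) + (seq_len(L) - 1L) * 4L
  sum(model$weights[idx])
}

#' Extract the scoring window around a splice site
#'
#' @param genome_seq Chromosome sequence (character).
#' @param site For donors the 0-based coordinate of the first intronic base
#'   (exon end boundary); for acceptors the 0-based coordinate of the first
#'   exonic base (intron end boundary). Both in genomic orientation for
#'   plus-strand genes; minus-strand windows are taken from the reverse
#'   complement.
#' @param side `"donor"` or `"acceptor"`.
#' @param strand `"+"` or `"-"`.
#' @return Window string (9 or 23 bases).
#' @export
splice_site_window <- function(genome_seq, site, side, strand = "+") {
  genome_seq <- as.character(genome_seq)
  if (strand == "+") {
    rng <- if (side == "donor") c(site - DONOR_EXONIC, site + DONOR_INTRONIC)
    else c(site - ACCEPTOR_INTRONIC, site + ACCEPTOR_EXONIC)
  } else {
    rng <- if (side == "donor") c(site - DONOR_INTRONIC, site + DONOR_EXONIC)
    else c(site - ACCEPTOR_EXONIC, site + ACCEPTOR_INTRONIC)
  }
  if (rng[1L] < 0L || rng[2L] > nchar(genome_seq))
    stop("splice-site window truncated by contig end")
  w <- substr(genome_seq, rng[1L] + 1L, rng[2L])
  if (strand == "-") w <- revcomp(w)
  w
}

#' Wild-type vs mutant splice-site strength difference
#'
#' @param variant List `pos` (0-based), `ref`, `alt` (single bases).
#' @param site Splice-site anchor coordinate (see [splice_site_window()]).
#' @param genome_seq Chromosome sequence.
#' @param model A `splice_strength_model`.
#' @param strand `"+"` or `"-"`.
#' @return List `score_wt`, `score_mut`, `delta` (`mut - wt`).
#' @export
strength_delta <- function(variant, site, genome_seq, model, strand = "+") {
  genome_seq <- as.character(genome_seq)
  side <- model$side
  wt <- splice_site_window(genome_seq, site, side, strand)
  # offset of the variant inside the plus-strand window interval
  if (strand == "+") {
    start <- if (side == "donor") site - DONOR_EXONIC else site - ACCEPTOR_INTRONIC
  } else {
    start <- if (side == "donor") site - DONOR_INTRONIC else site - ACCEPTOR_EXONIC
  }
  L <- ncol(model$probs)
  off <- variant$pos - start
  if (off < 0L || off >= L) stop("variant outside the scoring window")
  ref_g <- substr(as.character(genome_seq), variant$pos + 1L, variant$pos + 1L)
  if (!identical(toupper(ref_g), toupper(variant$ref)))
    stop("reference allele mismatch at position ", variant$pos)
  mut_seq_plus <- paste0(substr(genome_seq, start + 1L, start + off),
                         variant$alt,
                         substr(genome_seq, start + off + 2L, start + L))
  mut <- if (strand == "-") revcomp(mut_seq_plus) else mut_seq_plus
  sw <- score_splice_site(wt, model)
  sm <- score_splice_site(mut, model)
  list(score_wt = sw, score_mut = sm, delta = sm - sw)
}

#' Pyrimidine fraction of the polypyrimidine-tract region
#'
#' Companion readout to the acceptor 23-mer score: the C/T fraction of the
#' intronic +4..+20 region upstream of the acceptor.
#'
#' @param acceptor_window 23-mer from [splice_site_window()].
#' @return Fraction in `[0, 1]`.
#' @export
ppt_pyrimidine_fraction <- function(acceptor_window) {
  stopifnot(nchar(acceptor_window) == 23L)
  # window layout: positions 1..20 intronic (-20..-1), 21..23 exonic
  ppt <- substr(acceptor_window, 1L, 17L)  # -20..-4
  b <- strsplit(toupper(ppt), "")[[1L]]
  mean(b %in% c("C", "T"))
}
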