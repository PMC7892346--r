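# Auxiliary splice codes: exonic splicing enhancer / silencer hexamers.
# The 5 bp flanks on both sides of an SNV give an 11-mer whose six hexamer
# frames are matched against a motif set, separately for the wild-type and
# mutant allele; a sequence counts once per set no matter how many hexamers
# it matches.

#' Read a hexamer motif set
#'
#' @param path Text file, one hexamer per line (comments with `#`).
#' @param role `"enhancer"` or `"silencer"`.
#' @param name Set label (defaults to the file name).
#' @return List of class `motif_set` with `hexamers` (uppercase character
#'   vector), `role`, `name`.
#' @export
read_motif_set <- function(path, role, name = basename(path)) {
  x <- readLines(path)
  x <- toupper(trimws(sub("#.*", "", x)))
  x <- x[nzchar(x)]
  motif_set(x, role, name)
}

#' @rdname read_motif_set
#' @param hexamers Character vector of 6-mers over ACGT.
#' @export
motif_set <- function(hexamers, role, name = role) {
  hexamers <- unique(toupper(hexamers))
  if (any(nchar(hexamers) != 6L) ||
      any(!strsplit(paste(hexamers, collapse = ""), "")[[1L]] %in%
            c("A", "C", "G", "T")))
    stop("motif set must contain ACGT 6-mers")
  stopifnot(role %in% c("enhancer", "silencer"))
  structure(list(name = name, hexamers = hexamers, role = role),
            class = "motif_set")
}

#' Extract the +/-5 bp flank 11-mer around an SNV
#'
#' @param genome_seq Chromosome sequence.
#' @param pos 0-based SNV position.
#' @param alt Optional alternate base; when given the centre base is
#'   substituted.
#' @return 11-character string.
#' @export
flank_11mer <- function(genome_seq, pos, alt = NULL) {
  genome_seq <- as.character(genome_seq)
  if (pos - 5L < 0L || pos + 6L > nchar(genome_seq))
    stop("flank truncated by contig end")
  s <- substr(genome_seq, pos - 4L, pos + 6L)  # 1-based: pos-5+1 .. pos+6
  if (!is.null(alt)) substr(s, 6L, 6L) <- toupper(alt)
  s
}

#' Match wild-type and mutant SNV flanks against a motif set
#'
#' @param wt_11mer,mut_11mer Flank sequences from [flank_11mer()].
#' @param set A `motif_set`.
#' @return List `wt_matched`, `mut_matched` (character vectors of matching
#'   hexamers), `wt_hit`, `mut_hit` (logicals: the sequence counts once per
#'   set regardless of how many hexamers matched).
#' @export
motif_scan <- function(wt_11mer, mut_11mer, set) {
  frames <- function(s) {
    s <- toupper(s)
    stopifnot(nchar(s) == 11L)
    vapply(1:6, function(i) substr(s, i, i + 5L), "")
  }
  wm <- intersect(frames(wt_11mer), set$hexamers)
  mm <- intersect(frames(mut_11mer), set$hexamers)
  list(wt_matched = wm, mut_matched = mm,
       wt_hit = length(wm) > 0L, mut_hit = length(mm) > 0L)
}
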