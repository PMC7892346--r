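# Branchpoint analysis: U2 snRNA recognises the branchpoint region by
# base-pairing its GUGUAGUA motif with the 8 residues from 5 bp upstream to
# 3 bp downstream of the BP adenosine (the BP nucleotide itself is bulged
# out and excluded). Binding stability is summarised as a duplex free
# energy over a bundled nearest-neighbour stack table covering Watson-Crick
# and G.U wobble pairs; mismatched positions break stacking and add a fixed
# +1 kcal/mol penalty each. The table values are representative
# nearest-neighbour magnitudes: analyses built on this score interpret only
# signs and orderings of energy differences, not absolute energies.

U2_MOTIF <- "GUGUAGUA"
U2_MISMATCH_PENALTY <- 1.0

# Stack energies (kcal/mol) for adjacent base pairs, indexed by the pair
# formed at position i and at position i+1 (target strand 5'->3'). Pair
# codes give the target base first, the motif base second.
u2_stack_table <- local({
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(NA_real_, 6L, 6L, dimnames = list(pairs, pairs))
  base <- c(AU = -1.1, UA = -1.3, CG = -2.4, GC = -2.2, GU = -0.8, UG = -0.6)
  for (p in pairs) for (q in pairs) m[p, q] <- round((base[p] + base[q]) / 2, 2)
  # a few canonical stacks strengthened beyond the additive mean
  m["CG", "GC"] <- -3.3; m["GC", "CG"] <- -3.4
  m["AU", "UA"] <- -1.3; m["UA", "AU"] <- -1.1
  m
})

u2_pair_code <- function(target, motif) {
  p <- paste0(target, motif)
  if (p %in% rownames(u2_stack_table)) p else NA_character_
}

#' U2 snRNA duplex binding energy of a branchpoint window
#'
#' @param window_seq_8nt The 8 residues flanking the BP (5 upstream + 3
#'   downstream, BP excluded), 5' to 3'; T and U spellings are equivalent.
#' @return Duplex energy in kcal/mol-like units; lower (more negative)
#'   means more stable U2 binding.
#' @export
u2_binding_energy <- function(window_seq_8nt) {
  w <- chartr("Tt", "Uu", toupper(window_seq_8nt))
  if (nchar(w) != 8L) stop("branchpoint window must be 8 nt")
  tb <- strsplit(w, "")[[1L]]
  if (any(!tb %in% c("A", "C", "G", "U"))) stop("non-ACGU base in window")
  mb <- rev(strsplit(U2_MOTIF, "")[[1L]])  # antiparallel pairing
  codes <- vapply(seq_len(8L), function(i) u2_pair_code(tb[i], mb[i]), "")
  paired <- !is.na(codes)
  e <- U2_MISMATCH_PENALTY * sum(!paired)
  for (i in seq_len(7L)) {
    if (paired[i] && paired[i + 1L])
      e <- e + u2_stack_table[codes[i], codes[i + 1L]]
  }
  e
}

#' U2 binding energy change caused by a variant
#'
#' @param window_wt,window_mut Wild-type and mutant 8-nt BP windows.
#' @return List `dg_wt`, `dg_mut`, `ddg` (`mut - wt`; positive = binding
#'   destabilised).
#' @export
u2_delta_energy <- function(window_wt, window_mut) {
  dg_wt <- u2_binding_energy(window_wt)
  dg_mut <- u2_binding_energy(window_mut)
  list(dg_wt = dg_wt, dg_mut = dg_mut, ddg = dg_mut - dg_wt)
}

#' Annotate a variant to its nearest branchpoint
#'
#' Only variants 15-60 bp from the authentic acceptor junction are
#' annotated. The closest BP is chosen (ties to the lower genomic
#' coordinate) and the variant's position relative to the BP is reported
#' together with whether it falls in the -5..+3 window.
#'
#' @param variant_pos 0-based genomic position.
#' @param dist_to_acceptor Distance (bp, positive) from the variant to the
#'   authentic acceptor junction.
#' @param bp_positions Integer vector of annotated/predicted BP genomic
#'   positions in the same intron.
#' @param strand `"+"` or `"-"` (relative position is counted in
#'   transcript orientation: negative = 5' of the BP).
#' @param bp_window Window bounds (default -5..+3).
#' @return List `bp` (position), `relative` (signed offset), `in_window`
#'   (logical), or `NULL` when the variant is outside 15-60 bp from the
#'   acceptor or no BP is annotated.
#' @export
annotate_branchpoint <- function(variant_pos, dist_to_acceptor, bp_positions,
                                 strand = "+", bp_window = c(-5L, 3L)) {
  if (is.na(dist_to_acceptor) || dist_to_acceptor < 15L ||
      dist_to_acceptor > 60L) return(NULL)
  if (!length(bp_positions)) return(NULL)
  d <- abs(bp_positions - variant_pos)
  cand <- which(d == min(d))
  bp <- min(bp_positions[cand])  # tie-break: lower genomic coordinate
  rel <- if (strand == "+") variant_pos - bp else bp - variant_pos
  list(bp = bp, relative = as.integer(rel),
       in_window = rel >= bp_window[1L] && rel <= bp_window[2L])
}
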