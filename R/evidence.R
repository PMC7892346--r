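# Per-read splicing evidence: the contract between upstream read extraction
# (or the cohort simulator) and the detection statistics. One row per RNA
# read; junction reads carry the genomic (donor_end, acceptor_start) pairs
# they span, unspliced reads carry their genomic span, and reads overlapping
# a variant position carry the observed base and its quality.

EVIDENCE_COLS <- c("sample_id", "gene_id", "read_id", "kind", "junctions",
                   "span", "var_pos", "var_base", "base_qual")

#' Read a per-read splicing evidence table
#'
#' The TSV dialect has columns `sample_id, gene_id, read_id, kind, junctions,
#' span, var_pos, var_base, base_qual` with `"."` for absent fields;
#' `junctions` is a semicolon-joined list of 0-based `donor-acceptor` pairs
#' and `span` a 0-based half-open `start-end` interval.
#'
#' @param path TSV file path.
#' @return `data.table` of read observations (coordinates left encoded;
#'   see [parse_junctions()]).
#' @export
read_evidence_table <- function(path) {
  obs <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("sample_id", "gene_id", "read_id", "kind", "junctions",
                  "span", "var_base")))
  missing <- setdiff(EVIDENCE_COLS, names(obs))
  if (length(missing)) stop("evidence table lacks columns: ",
                            paste(missing, collapse = ", "))
  bad <- which(!obs$kind %in% c("junction", "unspliced_span"))
  if (length(bad)) stop("unknown kind '", obs$kind[bad[1L]], "' at line ",
                        bad[1L] + 1L)
  for (i in which(obs$kind == "junction")) {
    jm <- parse_junctions(obs$junctions[i])
    if (any(jm[, 2L] <= jm[, 1L]))
      stop("junction with acceptor_start <= donor_end at line ", i + 1L)
    if (nrow(jm) > 1L && any(diff(jm[, 1L]) <= 0))
      stop("junction pairs not ordered 5'->3' at line ", i + 1L)
  }
  qs <- obs$base_qual[obs$base_qual != "." & !is.na(obs$base_qual)]
  if (length(qs) && any(as.numeric(qs) < 0 | as.numeric(qs) > 60))
    stop("base quality outside [0, 60]")
  obs
}

#' @rdname read_evidence_table
#' @param obs Observation `data.table` as returned by [read_evidence_table()].
#' @param path Output path.
#' @export
write_evidence_table <- function(obs, path) {
  fwrite(as.data.table(obs)[, EVIDENCE_COLS, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Parse the junction or span encoding of an evidence row
#'
#' @param x A `junctions` string (`"d-a;d-a"`) or `span` string (`"s-e"`).
#' @return Integer matrix with one row per pair, or a 0-row matrix for `"."`.
#' @export
parse_junctions <- function(x) {
  if (is.na(x) || x == "." || x == "") {
    return(matrix(integer(0), ncol = 2L))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  matrix(as.integer(m), ncol = 2L)
}

encode_junctions <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(".")
  paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ";")
}

#' Classify one read as supporting normal or abnormal splicing
#'
#' A junction read is normal iff every junction it spans is annotated for
#' the gene; any novel junction makes it abnormal. An unspliced read
#' covering an exon-intron boundary by at least 5 bp on each side is
#' abnormal (intron-retention evidence); an unspliced read lying fully
#' inside exons is uninformative; one fully inside an intron counts as
#' retention evidence only when a junction boundary lies within one read
#' length of it.
#'
#' @param obs One evidence row (list or single-row data.table).
#' @param t `transcript_model` of the gene.
#' @param known Junction table from [known_junctions()].
#' @return List `class` (`"normal"`, `"abnormal"`, `"uninformative"`),
#'   `intron_idx` (locus assignment; `NA` when uninformative) and, for
#'   abnormal junction reads, `novel` (matrix of novel junction pairs).
#' @export
classify_read <- function(obs, t, known) {
  it <- transcript_introns(t)
  if (obs$kind == "junction") {
    jm <- parse_junctions(obs$junctions)
    kk <- paste(known$jx_start, known$jx_end)
    isk <- paste(jm[, 1L], jm[, 2L]) %in% kk
    # locus: intron containing (or bounded by) the first relevant junction
    locus_of <- function(a, b) {
      hit <- which(it$start <= a & it$end >= b)
      if (length(hit)) hit[1L] else {
        hit <- which(it$start >= a & it$end <= b)  # skipping-type junction
        if (length(hit)) hit[1L] else NA_integer_
      }
    }
    if (all(isk)) {
      return(list(class = "normal",
                  intron_idx = locus_of(jm[1L, 1L], jm[1L, 2L]),
                  novel = matrix(integer(0), ncol = 2L)))
    }
    nv <- jm[!isk, , drop = FALSE]
    return(list(class = "abnormal",
                intron_idx = locus_of(nv[1L, 1L], nv[1L, 2L]), novel = nv))
  }
  sp <- parse_junctions(obs$span)
  s <- sp[1L, 1L]; e <- sp[1L, 2L]
  if (nrow(it)) {
    for (k in seq_len(nrow(it))) {
      for (b in c(it$start[k], it$end[k])) {
        if (s <= b - 5L && e >= b + 5L)
          return(list(class = "abnormal", intron_idx = it$intron_idx[k],
                      novel = matrix(integer(0), ncol = 2L)))
      }
    }
    inside <- which(s >= it$start & e <= it$end)
    if (length(inside)) {
      k <- inside[1L]
      len <- e - s
      if (min(s - it$start[k], it$end[k] - e) <= len)
        return(list(class = "abnormal", intron_idx = it$intron_idx[k],
                    novel = matrix(integer(0), ncol = 2L)))
      return(list(class = "uninformative", intron_idx = NA_integer_,
                  novel = matrix(integer(0), ncol = 2L)))
    }
  }
  list(class = "uninformative", intron_idx = NA_integer_,
       novel = matrix(integer(0), ncol = 2L))
}

#' Classify every read of a gene/sample evidence table
#'
#' @param obs Evidence `data.table` (one gene).
#' @param t `transcript_model`.
#' @param known Optional precomputed [known_junctions()] table.
#' @return The table with `class` and `intron_idx` columns appended.
#' @export
classify_reads <- function(obs, t, known = known_junctions(t)) {
  obs <- as.data.table(obs)
  res <- lapply(seq_len(nrow(obs)), function(i) classify_read(obs[i], t, known))
  obs[, class := vapply(res, `[[`, "", "class")]
  obs[, intron_idx := vapply(res, `[[`, NA_integer_, "intron_idx")]
  obs
}

#' RNA allele counts at a variant position
#'
#' Counts observed bases among reads carrying allele information at the
#' position, discarding bases below the quality cutoff.
#'
#' @param obs Evidence rows with `var_pos`, `var_base`, `base_qual`.
#' @param pos 0-based variant position.
#' @param ref,alt Reference and variant alleles (single bases).
#' @param min_base_quality Quality cutoff (default 30).
#' @return Named integer vector `c(ref, alt, other)`; `other` tallies
#'   covering reads not counted toward either allele (low-quality bases and
#'   third alleles).
#' @export
rna_allele_counts <- function(obs, pos, ref, alt, min_base_quality = 30) {
  obs <- as.data.table(obs)
  has <- obs$var_pos != "." & !is.na(obs$var_pos) &
    suppressWarnings(as.integer(obs$var_pos)) == as.integer(pos)
  has[is.na(has)] <- FALSE
  sub <- obs[has]
  if (!nrow(sub)) return(c(ref = 0L, alt = 0L, other = 0L))
  q <- suppressWarnings(as.numeric(sub$base_qual))
  ok <- !is.na(q) & q >= min_base_quality
  b <- sub$var_base[ok]
  nref <- sum(b == ref); nalt <- sum(b == alt)
  c(ref = nref, alt = nalt, other = nrow(sub) - nref - nalt)
}
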