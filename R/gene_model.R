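#' @import data.table
#' @importFrom stats quantile pnorm sd rbeta rbinom rpois runif rnorm setNames
#'   p.adjust dhyper fisher.test wilcox.test ks.test
#' @importFrom utils head tail
NULL

# All genomic coordinates are handled internally as 0-based half-open
# intervals; GTF/VCF I/O converts at the boundary.

#' Construct a transcript model
#'
#' A transcript model carries the exon structure (and optionally the CDS) of
#' one isoform on a reference sequence, and is the coordinate frame for every
#' distance rule in the package (splice-site / proximal / deep intronic
#' classification, candidate windows, branchpoint windows, PTC positions).
#'
#' @param transcript_id,gene_id,chrom Identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of 0-based half-open
#'   genomic intervals. May be given in any order; they are stored sorted in
#'   transcript orientation (5' to 3'), i.e. descending genomic coordinate on
#'   the minus strand.
#' @param cds_start,cds_end Optional genomic CDS interval (0-based half-open,
#'   `cds_start < cds_end` in genomic orientation), or `NULL` for
#'   non-coding transcripts.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NULL, cds_end = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript '", transcript_id, "' has zero exons")
  if (any(exons[, "end"] <= exons[, "start"])) stop("empty or inverted exon")
  o <- order(exons[, "start"])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L) {
    if (any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
      stop("overlapping exons in transcript '", transcript_id, "'")
    gaps <- exons[-1L, "start"] - exons[-nrow(exons), "end"]
    if (any(gaps < 4L)) stop("intron shorter than 4 bp in '", transcript_id, "'")
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  if (!is.null(cds_start)) {
    stopifnot(!is.null(cds_end), cds_start < cds_end)
    inside <- any(cds_start >= exons[, "start"] & cds_start < exons[, "end"]) &&
      any(cds_end > exons[, "start"] & cds_end <= exons[, "end"])
    if (!inside) stop("CDS boundaries outside the exon union")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = if (is.null(cds_start)) NA_integer_ else as.integer(cds_start),
                 cds_end = if (is.null(cds_end)) NA_integer_ else as.integer(cds_end)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), CDS %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              if (is.na(x$cds_start)) "absent" else
                sprintf("[%d,%d)", x$cds_start, x$cds_end)))
  invisible(x)
}

#' Intron table of a transcript
#'
#' @param t A `transcript_model`.
#' @return `data.table` with one row per intron in transcript order:
#'   `intron_idx`, genomic `start`/`end` (0-based half-open), and the
#'   strand-aware `donor_end` (genomic boundary coordinate where the intron
#'   meets its upstream exon) and `acceptor_start` (boundary where it meets
#'   its downstream exon). On the plus strand `donor_end == start` and
#'   `acceptor_start == end`; roles swap on the minus strand.
#' @export
transcript_introns <- function(t) {
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.table(intron_idx = integer(), start = integer(),
                      end = integer(), donor_end = integer(),
                      acceptor_start = integer()))
  }
  if (t$strand == "+") {
    s <- ex[-n, "end"]; e <- ex[-1L, "start"]
    data.table(intron_idx = seq_len(n - 1L), start = s, end = e,
               donor_end = s, acceptor_start = e)
  } else {
    s <- ex[-1L, "end"]; e <- ex[-n, "start"]
    data.table(intron_idx = seq_len(n - 1L), start = s, end = e,
               donor_end = e, acceptor_start = s)
  }
}

#' Annotated exon-exon junction set of one or more isoforms
#'
#' @param transcripts A `transcript_model` or list of them (same gene).
#' @return `data.table` with columns `donor_end`, `acceptor_start`: the
#'   genomic coordinates flanking each annotated intron (0-based; a spliced
#'   read joining exon residue `donor_end - 1` to residue `acceptor_start`
#'   on the plus strand spans this junction).
#' @export
known_junctions <- function(transcripts) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  jx <- rbindlist(lapply(transcripts, function(t) {
    it <- transcript_introns(t)
    # junction key in genomic orientation: (intron start, intron end)
    data.table(jx_start = it$start, jx_end = it$end)
  }))
  unique(jx)
}

#' Load transcript models from a GTF stream
#'
#' Reads `exon` (and, when present, `CDS`) features and returns one
#' `transcript_model` per transcript, converted to the internal 0-based
#' half-open frame with strand-aware exon ordering.
#'
#' @param gtf_file Path to a GTF file.
#' @return Named list of `transcript_model` (names = transcript ids).
#' @export
load_gene_models <- function(gtf_file) {
  gr <- tryCatch(rtracklayer::import(gtf_file, format = "gtf"),
                 error = function(e) stop("malformed GTF '", gtf_file, "': ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("no exon features in '", gtf_file, "'")
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id))
  out <- list()
  for (tid in unique(dt$transcript_id)) {
    sub <- dt[dt$transcript_id == tid, ]
    ex <- sub[sub$type == "exon", ]
    if (nrow(ex) == 0L) {
      warning("transcript '", tid, "' has zero exons; skipped")
      next
    }
    cds <- sub[sub$type == "CDS", ]
    cs <- if (nrow(cds)) min(cds$start) else NULL
    ce <- if (nrow(cds)) max(cds$end) else NULL
    out[[tid]] <- transcript_model(tid, ex$gene_id[1L], ex$chrom[1L],
                                   ex$strand[1L],
                                   cbind(ex$start, ex$end), cs, ce)
  }
  out
}

#' Select the longest isoform of a gene
#'
#' Distance rules and event calls are reported on a single isoform per gene:
#' the one with the greatest summed exon length, ties broken by
#' lexicographically smallest transcript id.
#'
#' @param isoforms Non-empty list of `transcript_model` of one gene.
#' @return A single `transcript_model`.
#' @export
select_longest_isoform <- function(isoforms) {
  if (inherits(isoforms, "transcript_model")) return(isoforms)
  if (length(isoforms) == 0L) stop("no isoforms supplied")
  gid <- unique(vapply(isoforms, `[[`, "", "gene_id"))
  if (length(gid) != 1L) stop("isoforms belong to different genes")
  len <- vapply(isoforms, function(t) sum(t$exons[, "end"] - t$exons[, "start"]), 0)
  ids <- vapply(isoforms, `[[`, "", "transcript_id")
  cand <- which(len == max(len))
  isoforms[[cand[order(ids[cand])][1L]]]
}

#' Classify a variant position relative to exon-intron junctions
#'
#' Intronic positions 1-2 bp from the nearest junction are splice-site (SS)
#' positions, 3-20 bp proximal intronic, and >20 bp deep intronic; exonic
#' positions carry negative distances counted from the last exonic base (-1).
#' Intronic distances are counted from the first intronic base (+1) on the
#' relevant side; `side` records whether the nearest junction is a donor or
#' an acceptor (ties resolved to the donor side). Silent exonic SNVs within
#' 2 bp of a junction are flagged non-silent (`effective_silent = FALSE`).
#'
#' @param pos 0-based genomic position of the variant (deletions are located
#'   by their 5'-most deleted base).
#' @param t A `transcript_model` spanning `pos`.
#' @param is_silent Optional logical: coding-level silence of an exonic SNV.
#' @return List with `category` (one of `splice_site`, `proximal_intronic`,
#'   `deep_intronic`, `exonic`), signed `distance_bp`, `side`
#'   (`donor`/`acceptor`/`NA` for junction-less single-exon transcripts),
#'   `intron_idx` or `exon_idx`, and `effective_silent`.
#' @export
classify_variant_location <- function(pos, t, is_silent = NA) {
  pos <- as.integer(pos)
  ex <- t$exons
  span <- range(c(ex[, "start"], ex[, "end"]))
  if (pos < span[1L] || pos >= span[2L])
    stop("position ", pos, " outside transcript ", t$transcript_id)
  in_ex <- which(pos >= ex[, "start"] & pos < ex[, "end"])
  n <- nrow(ex)
  if (length(in_ex) == 1L) {
    j <- in_ex
    s <- ex[j, "start"]; e <- ex[j, "end"]
    # transcript-orientation junction roles at this exon's two genomic ends
    if (t$strand == "+") {
      d_don <- if (j < n) e - pos else NA_integer_      # downstream donor
      d_acc <- if (j > 1L) pos - s + 1L else NA_integer_ # upstream acceptor
    } else {
      d_don <- if (j < n) pos - s + 1L else NA_integer_
      d_acc <- if (j > 1L) e - pos else NA_integer_
    }
    cand <- c(donor = unname(d_don), acceptor = unname(d_acc))
    cand <- cand[!is.na(cand)]
    if (length(cand) == 0L) {
      return(list(category = "exonic", distance_bp = NA_integer_,
                  side = NA_character_, exon_idx = j,
                  effective_silent = isTRUE(is_silent)))
    }
    side <- names(cand)[which.min(cand)]
    if (length(cand) == 2L && cand[1L] == cand[2L]) side <- "donor"
    dist <- -min(cand)
    eff_sil <- if (is.na(is_silent)) NA else (isTRUE(is_silent) && dist < -2L)
    return(list(category = "exonic", distance_bp = as.integer(dist),
                side = side, exon_idx = j, effective_silent = eff_sil))
  }
  it <- transcript_introns(t)
  k <- which(pos >= it$start & pos < it$end)
  stopifnot(length(k) == 1L)
  s <- it$start[k]; e <- it$end[k]
  if (t$strand == "+") {
    pd <- pos - s + 1L   # +1 = first intron base 3' of the donor
    pa <- e - pos        # +1 = first intron base 5' of the acceptor
  } else {
    pd <- e - pos
    pa <- pos - s + 1L
  }
  side <- if (pd <= pa) "donor" else "acceptor"
  dist <- min(pd, pa)
  category <- if (dist <= 2L) "splice_site"
  else if (dist <= 20L) "proximal_intronic" else "deep_intronic"
  list(category = category, distance_bp = as.integer(dist), side = side,
       intron_idx = it$intron_idx[k],
       effective_silent = if (is.na(is_silent)) NA else FALSE)
}

#' Prefilter somatic variants against caller support and population databases
#'
#' Keeps variants called by at least two callers, drops common SNPs
#' (database minor allele frequency > 1%), and drops overlaps with known
#' rarer/unknown-frequency SNPs unless supported by at least two tumour
#' samples in a somatic recurrence catalogue.
#'
#' @param variants `data.table` with at least `chrom`, `pos` (0-based),
#'   `caller_count`; optional `db_maf`, `cosmic_recurrence` columns override
#'   table lookups.
#' @param snp_table Optional `data.table(chrom, pos, maf)`; `maf = NA` means
#'   a known SNP of unknown frequency. Missing table treated as empty.
#' @param cosmic_table Optional `data.table(chrom, pos, recurrence)`.
#' @return List `kept` (data.table) and `dropped` (data.table with a
#'   `reason` column: `single_caller`, `common_snp`, `snp_overlap`).
#' @export
prefilter_variants <- function(variants, snp_table = NULL, cosmic_table = NULL) {
  v <- as.data.table(variants)
  if (!nrow(v)) return(list(kept = v, dropped = copy(v)[, reason := character(0)]))
  key <- paste(v$chrom, v$pos)
  maf <- if ("db_maf" %in% names(v)) v$db_maf else rep(NA_real_, nrow(v))
  snp_hit <- rep(FALSE, nrow(v))
  if (!is.null(snp_table) && nrow(snp_table)) {
    st <- as.data.table(snp_table)
    skey <- paste(st$chrom, st$pos)
    m <- match(key, skey)
    snp_hit <- !is.na(m)
    maf <- ifelse(is.na(maf) & snp_hit, st$maf[m], maf)
  }
  snp_hit <- snp_hit | !is.na(maf)
  rec <- if ("cosmic_recurrence" %in% names(v)) v$cosmic_recurrence
         else rep(NA_integer_, nrow(v))
  if (!is.null(cosmic_table) && nrow(cosmic_table)) {
    ct <- as.data.table(cosmic_table)
    m <- match(key, paste(ct$chrom, ct$pos))
    rec <- ifelse(is.na(rec) & !is.na(m), ct$recurrence[m], rec)
  }
  rec[is.na(rec)] <- 0L
  reason <- rep(NA_character_, nrow(v))
  reason[snp_hit & !(rec >= 2L)] <- "snp_overlap"
  reason[!is.na(maf) & maf > 0.01] <- "common_snp"   # common SNPs never rescued
  reason[v$caller_count < 2L] <- "single_caller"
  kept <- v[is.na(reason)]
  dropped <- v[!is.na(reason)]
  drop_reasons <- reason[!is.na(reason)]
  dropped[, reason := drop_reasons]
  list(kept = kept, dropped = dropped)
}

#' Cohort sample QC on novel-junction burden and splicing-factor status
#'
#' Removes samples carrying pathogenic trans-acting splicing-factor
#' mutations, and samples whose fraction of novel-junction reads is an
#' outlier within their cancer type (z-score > 1.96 using the population
#' standard deviation).
#'
#' @param junction_stats `data.table(sample_id, cancer_type,
#'   novel_junction_fraction)`.
#' @param splicing_factor_flags Character vector of flagged sample ids
#'   (precomputed from variant calls over the factor regions), or `NULL`.
#' @return Character vector of retained sample ids.
#' @export
sample_qc <- function(junction_stats, splicing_factor_flags = NULL) {
  js <- as.data.table(junction_stats)
  js <- js[!(sample_id %in% splicing_factor_flags)]
  keep <- character(0)
  for (ct in unique(js$cancer_type)) {
    sub <- js[cancer_type == ct]
    if (nrow(sub) < 2L) {
      warning("cancer type '", ct, "' has <2 samples; z undefined, retained")
      keep <- c(keep, sub$sample_id)
      next
    }
    x <- sub$novel_junction_fraction
    sdev <- sqrt(mean((x - mean(x))^2))  # population SD
    z <- if (sdev > 0) (x - mean(x)) / sdev else rep(0, length(x))
    keep <- c(keep, sub$sample_id[z <= 1.96])
  }
  keep
}
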