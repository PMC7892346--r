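# File-format boundary: FASTA via Biostrings, GTF via a simple fixed-field
# emitter (read back with rtracklayer), VCF v4.2 emitter (read back with
# vcfR), variant/evidence/expression TSVs via data.table. All internal
# coordinates are 0-based half-open; GTF and VCF are written 1-based.

#' Write the simulated genome as FASTA
#' @param genome `sim_genome` (or a named character vector).
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "sim_genome")) genome$sequences else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a genome FASTA into the named-character form the package uses
#' @param path FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' Write transcript models as GTF
#' @param transcripts List of `transcript_model`.
#' @param path Output file.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (t in transcripts) {
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id,
                     t$transcript_id)
    ex <- t$exons[order(t$exons[, "start"]), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(t$chrom, "sim", "exon", ex[i, "start"] + 1L,
                              ex[i, "end"], ".", t$strand, ".", attr0,
                              sep = "\t"))
    }
    if (!is.na(t$cds_start)) {
      for (i in seq_len(nrow(ex))) {
        cs <- max(ex[i, "start"], t$cds_start)
        ce <- min(ex[i, "end"], t$cds_end)
        if (cs < ce)
          lines <- c(lines, paste(t$chrom, "sim", "CDS", cs + 1L, ce, ".",
                                  t$strand, ".", attr0, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write somatic variants as a minimal VCF v4.2
#' @param variants `data.table` with `chrom, pos, ref, alt, sample_id` (pos
#'   0-based internal).
#' @param path Output file.
#' @export
write_vcf <- function(variants, path) {
  v <- as.data.table(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Carrier sample\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSAMPLE=%s",
                  v$chrom, v$pos + 1L,
                  if ("variant_id" %in% names(v)) v$variant_id else ".",
                  v$ref, v$alt, v$sample_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read somatic variants from VCF (via vcfR) into the internal frame
#' @param path VCF file.
#' @return `data.table(variant_id, chrom, pos, ref, alt, sample_id)` with
#'   0-based positions.
#' @export
read_vcf_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.table(vcfR::getFIX(v))
  info <- vcfR::extract.info(v, "SAMPLE")
  data.table(variant_id = fx$ID, chrom = fx$CHROM,
             pos = as.integer(fx$POS) - 1L, ref = fx$REF, alt = fx$ALT,
             sample_id = info)
}

#' Read/write a MAF-like variant TSV
#'
#' Columns `chrom, pos, ref, alt, sample, t_ref_count, t_alt_count,
#' callers` with 1-based positions on disk.
#'
#' @param path TSV file.
#' @return `data.table` in internal (0-based) form with the package's
#'   column names.
#' @export
read_variants_tsv <- function(path) {
  x <- fread(path, sep = "\t")
  data.table(variant_id = if ("variant_id" %in% names(x)) x$variant_id
             else sprintf("v%03d", seq_len(nrow(x))),
             chrom = x$chrom, pos = x$pos - 1L, ref = x$ref, alt = x$alt,
             kind = ifelse(nchar(x$ref) == 1L & nchar(x$alt) == 1L,
                           "SNV", "deletion"),
             sample_id = x$sample,
             dna_ref_count = x$t_ref_count, dna_alt_count = x$t_alt_count,
             caller_count = x$callers)
}

#' @rdname read_variants_tsv
#' @param variants Internal-form variant `data.table`.
#' @export
write_variants_tsv <- function(variants, path) {
  v <- as.data.table(variants)
  out <- data.table(chrom = v$chrom, pos = v$pos + 1L, ref = v$ref,
                    alt = v$alt, sample = v$sample_id,
                    t_ref_count = v$dna_ref_count,
                    t_alt_count = v$dna_alt_count,
                    callers = v$caller_count, variant_id = v$variant_id)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write pseudoexon / retained-segment calls as BED
#' @param calls Pipeline calls table.
#' @param path Output file.
#' @export
write_events_bed <- function(calls, path) {
  dt <- as.data.table(calls)
  dt <- dt[!is.na(event_type) & !is.na(cryptic_acceptor) |
             !is.na(cryptic_donor)]
  lines <- character(0)
  for (i in seq_len(nrow(dt))) {
    r <- dt[i]
    if (!is.na(r$cryptic_acceptor) && !is.na(r$cryptic_donor)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s_%s", r$chrom,
                                min(r$cryptic_acceptor, r$cryptic_donor),
                                max(r$cryptic_acceptor, r$cryptic_donor),
                                r$variant_id, r$event_type))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
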