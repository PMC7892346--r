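test_that("transcript models enforce exon structure and expose introns", {
  t <- toy_two_exon()
  expect_equal(nrow(t$exons), 2L)
  it <- transcript_introns(t)
  expect_equal(it$start, 200L)
  expect_equal(it$end, 500L)
  expect_equal(it$end - it$start, 300L)
  expect_equal(it$donor_end, 200L)
  expect_equal(it$acceptor_start, 500L)
  # minus strand: donor of intron 1 at the higher genomic coordinate
  tm <- toy_two_exon("-")
  itm <- transcript_introns(tm)
  expect_equal(itm$donor_end, 500L)
  expect_equal(itm$acceptor_start, 200L)
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0L, 10L), c(12L, 20L))),
               "intron")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0L, 10L), c(5L, 20L))),
               "overlap")
})

test_that("GTF round-trip preserves coordinates and CDS", {
  st <- small_study()
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(st$genome$transcripts, gtf)
  models <- load_gene_models(gtf)
  expect_length(models, length(st$genome$transcripts))
  t0 <- st$genome$transcripts[[1]]
  t1 <- models[[t0$transcript_id]]
  expect_equal(t1$exons, t0$exons, ignore_attr = TRUE)
  expect_equal(t1$cds_start, t0$cds_start)
  expect_equal(t1$cds_end, t0$cds_end)
  expect_equal(t1$strand, t0$strand)
})

test_that("longest isoform selection uses summed exon length with id tie-break", {
  a <- transcript_model("txA", "g", "c", "+", rbind(c(0L, 900L)))
  b <- transcript_model("txB", "g", "c", "+", rbind(c(0L, 600L), c(700L, 1300L)))
  expect_equal(select_longest_isoform(list(a, b))$transcript_id, "txB")
  expect_equal(select_longest_isoform(list(a))$transcript_id, "txA")
  tie1 <- transcript_model("txZ", "g", "c", "+", rbind(c(0L, 800L)))
  tie2 <- transcript_model("txY", "g", "c", "+", rbind(c(100L, 900L)))
  expect_equal(select_longest_isoform(list(tie1, tie2))$transcript_id, "txY")
  expect_error(select_longest_isoform(list()), "no isoforms")
})

test_that("variant location classification partitions by the 1-2/3-20/>20 rule", {
  t <- toy_two_exon()
  # donor side of the intron: +1 = first intron base (200)
  cases <- list(
    list(pos = 200L, cat = "splice_site", d = 1L, side = "donor"),
    list(pos = 201L, cat = "splice_site", d = 2L, side = "donor"),
    list(pos = 202L, cat = "proximal_intronic", d = 3L, side = "donor"),
    list(pos = 203L, cat = "proximal_intronic", d = 4L, side = "donor"),
    list(pos = 219L, cat = "proximal_intronic", d = 20L, side = "donor"),
    list(pos = 220L, cat = "deep_intronic", d = 21L, side = "donor"),
    # acceptor side: +1 = last intron base (499)
    list(pos = 499L, cat = "splice_site", d = 1L, side = "acceptor"),
    list(pos = 480L, cat = "proximal_intronic", d = 20L, side = "acceptor"),
    list(pos = 479L, cat = "deep_intronic", d = 21L, side = "acceptor"),
    # exonic: -1 = last exon base before the donor
    list(pos = 199L, cat = "exonic", d = -1L, side = "donor"),
    list(pos = 198L, cat = "exonic", d = -2L, side = "donor"),
    list(pos = 500L, cat = "exonic", d = -1L, side = "acceptor"))
  for (cs in cases) {
    lc <- classify_variant_location(cs$pos, t)
    expect_equal(lc$category, cs$cat, info = cs$pos)
    expect_equal(lc$distance_bp, cs$d, info = cs$pos)
    expect_equal(lc$side, cs$side, info = cs$pos)
  }
  expect_error(classify_variant_location(50L, t), "outside")
})

test_that("distances are mirror-symmetric between strands", {
  t <- toy_two_exon()
  tm <- mirror_transcript(t)
  for (pos in c(150L, 199L, 200L, 210L, 350L, 499L, 550L)) {
    lp <- classify_variant_location(pos, t)
    lm <- classify_variant_location(mirror_pos(t, pos), tm)
    expect_equal(lm$category, lp$category, info = pos)
    expect_equal(lm$distance_bp, lp$distance_bp, info = pos)
    expect_equal(lm$side, lp$side, info = pos)
  }
})

test_that("silent exonic SNVs within 2 bp of a junction are flagged non-silent", {
  t <- toy_two_exon()
  expect_false(classify_variant_location(198L, t, is_silent = TRUE)$effective_silent)
  expect_true(classify_variant_location(150L, t, is_silent = TRUE)$effective_silent)
  expect_false(classify_variant_location(150L, t, is_silent = FALSE)$effective_silent)
})

test_that("variant prefilter applies caller, SNP and recurrence rules", {
  v <- data.table(
    variant_id = sprintf("v%d", 1:5),
    chrom = "c", pos = c(10L, 20L, 30L, 40L, 50L),
    caller_count = c(1L, 3L, 3L, 3L, 2L),
    db_maf = c(NA, 0.02, NA, NA, NA),
    cosmic_recurrence = c(NA, NA, 3L, 0L, NA))
  snp <- data.table(chrom = "c", pos = c(30L, 40L), maf = c(0.002, NA))
  res <- prefilter_variants(v, snp_table = snp)
  expect_setequal(res$kept$variant_id, c("v3", "v5"))
  expect_equal(res$dropped[variant_id == "v1", reason], "single_caller")
  expect_equal(res$dropped[variant_id == "v2", reason], "common_snp")
  expect_equal(res$dropped[variant_id == "v4", reason], "snp_overlap")
})

test_that("sample QC removes novel-junction outliers and flagged samples", {
  js <- data.table(sample_id = sprintf("s%02d", 1:20),
                   cancer_type = "lymphoid",
                   novel_junction_fraction = c(rep(0.01, 19), 0.10))
  kept <- sample_qc(js)
  expect_false("s20" %in% kept)
  expect_length(kept, 19L)
  kept2 <- sample_qc(js, splicing_factor_flags = "s01")
  expect_false("s01" %in% kept2)
  # all-equal fractions: z undefined direction, nobody removed
  js[, novel_junction_fraction := 0.01]
  expect_length(sample_qc(js), 20L)
  # a sample exactly at the type mean is kept
  js2 <- data.table(sample_id = c("a", "b", "c"), cancer_type = "t",
                    novel_junction_fraction = c(0.01, 0.02, 0.03))
  expect_true("b" %in% sample_qc(js2))
  expect_warning(sample_qc(data.table(sample_id = "x", cancer_type = "solo",
                                      novel_junction_fraction = 0.5)),
                 "<2 samples")
})
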