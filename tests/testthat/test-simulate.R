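test_that("generated genomes satisfy the splice-code invariants", {
  st <- small_study()
  g <- st$genome
  for (gid in names(g$sequences)) {
    t <- g$transcripts[[paste0(gid, ".t1")]]
    s <- g$sequences[[gid]]
    it <- transcript_introns(t)
    for (k in seq_len(nrow(it))) {
      expect_equal(substr(s, it$start[k] + 1L, it$start[k] + 2L), "GT")
      expect_equal(substr(s, it$end[k] - 1L, it$end[k]), "AG")
      bp <- g$bp_annotation[chrom == gid & intron_idx == k]
      d_acc <- it$end[k] - bp$pos
      expect_gte(d_acc, 18L)
      expect_lte(d_acc, 40L)
      expect_equal(substr(s, bp$pos + 1L, bp$pos + 1L), "A")  # BP adenosine
    }
    expect_false(is.na(t$cds_start))
  }
})

test_that("genome generation is deterministic under the seed", {
  cfg <- sim_config(n_genes = 3L)
  g1 <- generate_genome(cfg, seed = 55L)
  g2 <- generate_genome(cfg, seed = 55L)
  expect_identical(g1$sequences, g2$sequences)
  g3 <- generate_genome(cfg, seed = 56L)
  expect_false(identical(g1$sequences, g3$sequences))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_genome_fasta(f1), g1$sequences)
})

test_that("injected mutations are class-consistent with the sequence edit", {
  st <- small_study()
  led <- st$ledger
  g <- st$genome
  expect_equal(nrow(led), 10L)
  for (j in seq_len(nrow(led))) {
    row <- led[j]
    s <- g$sequences[[row$chrom]]
    expect_equal(substr(s, row$pos + 1L, row$pos + 1L), row$ref)
    expect_true(row$ref != row$alt)
    t <- g$transcripts[[paste0(row$gene_id, ".t1")]]
    loc <- classify_variant_location(row$pos, t)
    if (row$class %in% c("donor_disrupt", "ppt_disrupt", "acceptor_disrupt"))
      expect_true(loc$category %in% c("proximal_intronic", "splice_site"),
                  info = row$class)
    if (row$class == "ss_dinucleotide")
      expect_equal(loc$category, "splice_site")
    if (row$class %in% c("bp_disrupt", "cryptic_donor_gain",
                         "cryptic_acceptor_gain", "cryptic_ppt_gain",
                         "enhancer_gain", "silencer_loss", "neutral"))
      expect_equal(loc$category, "deep_intronic", info = row$class)
  }
  # cryptic sites carry the required dinucleotides in the reference
  don <- led[class == "cryptic_donor_gain"]
  s <- g$sequences[[don$chrom]]
  expect_equal(substr(s, don$cryptic_donor + 1L, don$cryptic_donor + 2L), "GT")
  acc <- led[class == "cryptic_acceptor_gain"]
  s2 <- g$sequences[[acc$chrom]]
  expect_equal(substr(s2, acc$cryptic_acceptor - 1L, acc$cryptic_acceptor),
               "AG")
})

test_that("GC-to-GT injection rewrites the cassette donor and is audited", {
  cfg <- sim_config(n_genes = 2L)
  g <- generate_genome(cfg, seed = 77L)
  inj <- inject_mutations(g, "cryptic_donor_gain", seed = 78L,
                          mechanism = "gc_to_gt")
  row <- inj$ledger[1]
  s <- inj$genome$sequences[[row$chrom]]
  expect_equal(substr(s, row$cryptic_donor + 1L, row$cryptic_donor + 2L), "GC")
  expect_equal(row$ref, "C"); expect_equal(row$alt, "T")
  ev <- intended_event_object(row, inj$genome)
  ev <- locate_cryptic_sites(ev, s, "+",
                             list(pos = row$pos, ref = row$ref, alt = row$alt))
  expect_equal(ev$donor_origin, "created_by_variant")
})

test_that("cohort backgrounds follow the configured Beta law and are seed-stable", {
  st <- small_study()
  sup <- st$cohort$support
  wt <- sup[!(paste(gene_id, intron_idx, sample_id) %in%
                st$ledger[, paste(gene_id, intron_idx, sample_id)])]
  ratios <- wt[, abnormal_count / pmax(abnormal_count + normal_count, 1L)]
  expect_lt(abs(mean(ratios) - 0.01), 0.002)
  co2 <- simulate_cohort(st$genome, st$ledger, st$cfg, seed = 403L)
  expect_identical(st$cohort$support, co2$support)
  expect_identical(st$cohort$reads, co2$reads)
  f1 <- tempfile(); write_evidence_table(st$cohort$reads, f1)
  f2 <- tempfile(); write_evidence_table(co2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("carrier samples express the injected ratio with linked alleles", {
  st <- small_study()
  led <- st$ledger[!is.na(intended_event)]
  for (j in seq_len(nrow(led))) {
    row <- led[j]
    sup <- st$cohort$support[gene_id == row$gene_id &
                              intron_idx == row$intron_idx &
                              sample_id == row$sample_id]
    tot <- sup$abnormal_count + sup$normal_count
    # binomial draw around the intended ratio
    expect_lt(abs(sup$abnormal_count / tot - row$intended_ratio), 0.35)
    rd <- st$cohort$reads[sample_id == row$sample_id &
                            gene_id == row$gene_id & var_base != "."]
    if (nrow(rd)) expect_true(all(rd$var_base == row$alt))  # fidelity 1
  }
})

test_that("variant I/O round-trips through VCF and the MAF-like TSV", {
  st <- small_study()
  v <- st$cohort$variants
  fv <- tempfile(fileext = ".vcf")
  write_vcf(v, fv)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    back <- read_vcf_variants(fv)
    expect_equal(back$pos, v$pos)
    expect_equal(back$chrom, v$chrom)
    expect_equal(back$sample_id, v$sample_id)
  }
  ft <- tempfile(fileext = ".tsv")
  write_variants_tsv(v, ft)
  back2 <- read_variants_tsv(ft)
  expect_equal(back2$pos, v$pos)
  expect_equal(back2$ref, v$ref)
  expect_equal(back2$dna_alt_count, v$dna_alt_count)
  expect_equal(back2$kind, v$kind)
})
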