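test_that("position log-odds scoring matches a hand computation with add-one smoothing", {
  # uniform model: every base equally likely -> score 0 for any window
  unif <- train_splice_model(c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG",
                               "TTTTTTTTT"), "donor")
  expect_equal(score_splice_site("ACGTACGTA", unif), 0, tolerance = 1e-12)
  # 4-sequence training set, hand-summed log2((count+1)/(n+4) / 0.25)
  tr <- c("AAGGTAAGT", "CAGGTAAGT", "AAGGTGAGT", "TACGTAAGT")
  m <- train_splice_model(tr, "donor")
  q <- "AAGGTAAGT"
  counts <- sapply(1:9, function(i)
    sum(substr(tr, i, i) == substr(q, i, i)))
  hand <- sum(log2((counts + 1) / (4 + 4) / 0.25))
  expect_equal(score_splice_site(q, m), hand, tolerance = 1e-12)
  # per-position argmax consensus scores at least as high as any window
  cons <- paste(sapply(1:9, function(i)
    names(which.max(m$probs[, i]))), collapse = "")
  set.seed(3)
  for (i in 1:30) {
    w <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    expect_gte(score_splice_site(cons, m), score_splice_site(w, m))
  }
  expect_error(score_splice_site("ACGT", m), "length")
  expect_error(score_splice_site("ACGTNACGT", m), "non-ACGT")
})

test_that("model files load through the same interface as trained models", {
  tr <- c("AAGGTAAGT", "CAGGTAAGT", "AAGGTGAGT", "TACGTAAGT")
  m <- train_splice_model(tr, "donor")
  f <- tempfile(fileext = ".tsv")
  tab <- data.table(pos = 1:9, t(m$probs))
  fwrite(tab, f, sep = "\t")
  m2 <- load_splice_model(f, "donor")
  expect_equal(score_splice_site("AAGGTAAGT", m2),
               score_splice_site("AAGGTAAGT", m), tolerance = 1e-9)
})

test_that("a single-base change shifts the score by exactly the two position terms", {
  st <- small_study()
  models <- default_strength_models(st$genome)
  m <- models$donor
  w1 <- "CAGGTAAGT"; w2 <- "CAGGTCAGT"   # position 6 A->C
  expect_equal(score_splice_site(w2, m) - score_splice_site(w1, m),
               unname(m$weights["C", 6] - m$weights["A", 6]), tolerance = 1e-12)
})

test_that("strength deltas have the class-expected signs on simulator truth", {
  st <- small_study()
  sc <- score_truth_classes(st$genome, st$ledger)
  gains <- sc[class %in% c("cryptic_donor_gain", "cryptic_acceptor_gain",
                           "cryptic_ppt_gain")]
  expect_true(all(gains$value > 0))
  losses <- sc[class %in% c("donor_disrupt", "ss_dinucleotide",
                            "acceptor_disrupt", "ppt_disrupt")]
  expect_true(all(losses$value < 0))
  bp <- sc[class == "bp_disrupt"]
  expect_true(all(bp$value > 0))   # ddG: destabilised U2 binding
  expect_true(all(sc[class == "enhancer_gain", value] == 1))
  expect_true(all(sc[class == "silencer_loss", value] == 1))
})

test_that("strength_delta validates the window and the reference allele", {
  st <- small_study()
  g <- st$genome
  models <- default_strength_models(g)
  t <- g$transcripts[[1]]
  it <- transcript_introns(t)
  don <- it$donor_end[1]
  seqs <- g$sequences[[t$chrom]]
  ref <- substr(seqs, don + 3L, don + 3L)   # intronic +3 (0-based don+2)
  d0 <- strength_delta(list(pos = don + 2L, ref = ref, alt = ref), don,
                       seqs, models$donor)
  expect_equal(d0$delta, 0)
  expect_error(strength_delta(list(pos = don + 50L, ref = "A", alt = "C"),
                              don, seqs, models$donor), "outside")
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(strength_delta(list(pos = don + 2L, ref = wrong, alt = "G"),
                              don, seqs, models$donor), "mismatch")
})

test_that("U2 duplex energy is minimal at the perfect complement and rises under any mutation", {
  perfect <- "TACTACAC"   # reverse complement of GUGUAGUA
  e0 <- u2_binding_energy(perfect)
  expect_lt(e0, 0)
  # T/U spelling invariance
  expect_equal(u2_binding_energy("UACUACAC"), e0)
  # exhaustive: all 24 single mutations strictly raise the energy
  for (i in 1:8) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(perfect, i, i))) {
      w <- perfect
      substr(w, i, i) <- b
      expect_gt(u2_binding_energy(w), e0)
    }
  }
  # zero complementary positions: energy is 8 mismatch penalties
  expect_equal(u2_binding_energy("CCACCACA"), 8 * 1.0)
  expect_error(u2_binding_energy("ACGT"), "8 nt")
})

test_that("branchpoint annotation picks the nearest BP within 15-60 bp of the acceptor", {
  ann <- annotate_branchpoint(1032L, 32L, bp_positions = c(1030L, 990L))
  expect_equal(ann$bp, 1030L)
  expect_equal(ann$relative, 2L)
  expect_true(ann$in_window)
  # equidistant BPs: lower genomic coordinate
  tie <- annotate_branchpoint(1020L, 30L, bp_positions = c(1010L, 1030L))
  expect_equal(tie$bp, 1010L)
  expect_null(annotate_branchpoint(1032L, 10L, bp_positions = 1030L))
  expect_null(annotate_branchpoint(1032L, 61L, bp_positions = 1030L))
  out <- annotate_branchpoint(1040L, 40L, bp_positions = 1030L)
  expect_false(out$in_window)   # +10 outside -5..+3
})

test_that("motif scanning tests all six frames and counts a sequence once", {
  set <- motif_set(c("GAAGAA", "CCCCCC"), "enhancer")
  ms <- motif_scan("ACACAGAAGAA", "ACACAGATGAA", set)
  expect_true(ms$wt_hit)
  expect_false(ms$mut_hit)
  expect_equal(ms$wt_matched, "GAAGAA")
  # two overlapping matches still one hit
  ms2 <- motif_scan("GAAGAAGAAGA", "TTTTTTTTTTT", set)
  expect_true(ms2$wt_hit)
  expect_false(ms2$mut_hit)
  ms3 <- motif_scan("ACACACACACA", "ACACACACACA", set)
  expect_false(ms3$wt_hit && ms3$mut_hit)
  expect_error(motif_set(c("TOOLONG7"), "enhancer"))
})

test_that("flank extraction returns the +/-5 bp 11-mer with allele substitution", {
  s <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  w <- flank_11mer(s, 20L)
  expect_equal(nchar(w), 11L)
  expect_equal(substr(w, 6, 6), substr(s, 21, 21))
  wm <- flank_11mer(s, 20L, alt = "T")
  expect_equal(substr(wm, 6, 6), "T")
  expect_error(flank_11mer(s, 2L), "truncated")
})

test_that("PPT pyrimidine fraction reads the +4..+20 intronic region", {
  w <- paste0(strrep("T", 17), "CAG", "GAA")
  expect_equal(ppt_pyrimidine_fraction(w), 1)
  w2 <- paste0(strrep("G", 17), "CAG", "GAA")
  expect_equal(ppt_pyrimidine_fraction(w2), 0)
})
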