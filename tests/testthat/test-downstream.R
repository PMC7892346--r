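test_that("permutation enrichment handles the worked 4-SNV example exactly", {
  hits <- c(a = TRUE, b = FALSE, c = FALSE, d = FALSE)
  # observed draw of 2 containing the single hit; 3 of the 6 possible draws
  # contain it, so the exact P is 0.5
  r <- permutation_enrichment(c("a", "b"), names(hits), hits,
                              exhaustive = TRUE)
  expect_equal(r$p_value, 0.5)
  expect_equal(r$observed_count, 1L)
  # zero observed hits: every permutation count >= 0
  r0 <- permutation_enrichment(c("b", "c"), names(hits), hits,
                               exhaustive = TRUE)
  expect_equal(r0$p_value, 1.0)
  # sampled version approaches the exact value and is seed-reproducible
  r1 <- permutation_enrichment(c("a", "b"), names(hits), hits,
                               n_permutations = 4000L, seed = 9L)
  r2 <- permutation_enrichment(c("a", "b"), names(hits), hits,
                               n_permutations = 4000L, seed = 9L)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value, 0.5, tolerance = 0.05)
  expect_error(permutation_enrichment(c("a", "zz"), names(hits), hits),
               "subset")
})

test_that("unique-sequence counting de-duplicates identical flanks", {
  hits <- c(a = TRUE, b = TRUE, c = FALSE)
  seqs <- c(a = "ACGTACGTACG", b = "ACGTACGTACG", c = "TTTTTTTTTTT")
  r <- permutation_enrichment(c("a", "b"), names(hits), hits,
                              sequences = seqs, exhaustive = TRUE)
  expect_equal(r$observed_count, 1L)   # two hits, one unique sequence
})

test_that("PTC scan reconstructs aberrant transcripts and classifies NMD", {
  # contig for the 5-exon coding toy (exons 60 nt at 0,150,...; CDS 15..650)
  set.seed(11)
  base <- sample(c("A", "C", "G"), 800, TRUE)  # no T -> no stops by default
  t <- toy_coding()
  # place ATG at CDS start and a genuine stop at the annotated position
  base[16:18] <- c("A", "T", "G")
  base[649:651] <- c("T", "A", "A")
  s <- paste(base, collapse = "")
  # frame-preserving, stop-free pseudoexon (length 30): no PTC
  ev_pe <- structure(list(event_type = "pseudoexon_activation",
                          intron_idx = 2L, pseudoexon = c(250L, 280L)),
                     class = "splice_event")
  pc <- ptc_scan(ev_pe, t, s)
  expect_equal(pc$nmd_class, "none")
  # pseudoexon carrying an in-frame stop -> PTC at a computable position
  s2 <- s
  # exon2 ends at CDS nt 105 (genomic 150..210 spans CDS offsets 45..105);
  # pseudoexon inserted after exon 2 starts at aberrant CDS nt 106
  substr(s2, 251, 253) <- "TAA"   # first codon of the pseudoexon (in frame)
  pc2 <- ptc_scan(ev_pe, t, s2)
  expect_equal(pc2$ptc_cds_position, 106L)
  expect_equal(pc2$nmd_class, "insensitive")  # within the first 250 CDS nt
  # frame-shifting retained intron: first downstream stop is the PTC
  ev_ret <- structure(list(event_type = "full_intron_retention",
                           intron_idx = 2L), class = "splice_event")
  s3 <- s
  substr(s3, 262, 264) <- "TGA"
  pc3 <- ptc_scan(ev_ret, t, s3)
  expect_false(is.na(pc3$ptc_cds_position))
  # combinatorial with inconsistent sub-events is excluded
  comb <- structure(list(event_type = "combinatorial",
                         sub_events = list(ev_pe, structure(
                           list(event_type = "pseudoexon_activation",
                                intron_idx = 2L, pseudoexon = c(250L, 280L)),
                           class = "splice_event"))), class = "splice_event")
  substr(s2, 251, 253) <- "TAA"
  pc4 <- ptc_scan(comb, t, s2)
  expect_equal(pc4$nmd_class, pc2$nmd_class)  # consistent sub-events agree
})

test_that("NMD classification matches a brute-force rule over a 10-exon toy", {
  # 10 exons of 100 nt; CDS = the whole transcript for simplicity
  exon_len <- rep(100L, 10L)
  last_junction_cds <- sum(exon_len[-10L])   # 900
  brute <- function(ptc) {
    insens <- FALSE
    if (ptc <= 250L) insens <- TRUE
    region_start <- last_junction_cds - 55L
    if (ptc >= region_start) insens <- TRUE
    if (insens) "insensitive" else "sensitive"
  }
  for (ptc in seq_len(sum(exon_len))) {
    expect_equal(nmd_classify(ptc, last_junction_cds), brute(ptc), info = ptc)
  }
  # both clauses are exercised
  expect_equal(nmd_classify(120L, 900L), "insensitive")
  expect_equal(nmd_classify(845L, 900L), "insensitive")
  expect_equal(nmd_classify(600L, 900L), "sensitive")
  # single-exon transcript: no junction, never NMD
  expect_equal(nmd_classify(600L, NA_integer_), "insensitive")
})

test_that("expression effect requires five wild-type controls", {
  r <- expression_effect(5, rep(10, 5))
  expect_equal(r$log2_ratio, -1)
  r2 <- expression_effect(5, rep(10, 4))
  expect_true(is.na(r2$log2_ratio))
  expect_equal(r2$reason, "too_few_wildtype")
  set.seed(21)
  cmp <- expression_class_compare(rnorm(30), rnorm(30))
  expect_gt(cmp$p_value, 0.05)
})

test_that("gene burden summary computes class shares with the >5% filter", {
  calls <- data.table(
    gene_id = c(rep("TSG1", 10), rep("TSG2", 4)),
    sample_id = c(sprintf("s%02d", 1:10), sprintf("t%02d", 1:4)),
    tissue = "lymphoid",
    class = c(rep("intronic_missplicing", 2), rep("truncating", 8),
              rep("truncating", 4)))
  b <- gene_burden_summary(calls)
  expect_equal(b[gene_id == "TSG1", share_intronic_missplicing], 0.2)
  expect_equal(b[gene_id == "TSG1", n_mutant_samples], 10L)
  bf <- gene_burden_summary(calls, min_share = 0.05)
  expect_equal(bf$gene_id, "TSG1")
})

test_that("NMD-sensitive calls depress expression in the simulated cohort", {
  st <- small_study()
  led <- st$ledger[ptc_expectation %in% "sensitive"]
  expect_gt(nrow(led), 0L)   # deterministic fixture seed includes such rows
  for (j in seq_len(nrow(led))) {
    e <- st$cohort$expression
    mut <- e[gene_id == led$gene_id[j] & sample_id == led$sample_id[j], expr]
    wt <- e[gene_id == led$gene_id[j] & sample_id != led$sample_id[j], expr]
    eff <- expression_effect(mut, wt)
    expect_lt(eff$log2_ratio, 0)
  }
})
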